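#' Bray-Curtis dissimilarity between survey sites
#'
#' Pairwise Bray-Curtis distance
#' \eqn{d(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}
#' between site abundance vectors, computed with \pkg{vegan}. A pair of
#' all-zero sites is defined as distance 0 (identical emptiness) and the
#' affected pairs are flagged in the `zero_pairs` attribute.
#'
#' @param m sites x species matrix or data.frame of non-negative abundances
#'   (row names are site ids).
#' @return a symmetric `dist`-backed matrix of class `bray_curtis`, entries
#'   in \[0,1\], zero diagonal.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("at least 2 sites required")
  if (any(m < 0)) stop("abundances must be non-negative")
  empty <- rowSums(m) == 0
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  dm <- as.matrix(d)
  zero_pairs <- which(outer(empty, empty, `&`) & upper.tri(dm),
                      arr.ind = TRUE)
  dm[outer(empty, empty, `&`)] <- 0   # 0/0 pairs: identical emptiness
  diag(dm) <- 0
  structure(dm, class = c("bray_curtis", "matrix"),
            zero_pairs = zero_pairs)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation r of the corresponding lower-triangle entries of two
#' site-matched distance matrices, with significance from jointly permuting
#' the rows and columns of the second matrix (\pkg{vegan}'s Mantel
#' machinery). The p-value uses the add-one rule
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})} for the
#' one-tailed (`greater`) default; `two_sided` compares absolute values.
#'
#' @param d1,d2 distance matrices (`dist`, matrix, or [bray_curtis()]) over
#'   the same sites in the same order.
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed for reproducibility.
#' @param tail `"greater"` (default) or `"two_sided"`.
#' @return a `mantel_result`: `r`, `p`, `n_perm`, `seed`, `tail`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999L, seed = 1L,
                        tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  as_d <- function(d) {
    if (inherits(d, "dist")) return(d)
    d <- unclass(as.matrix(d))
    if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix not symmetric")
    stats::as.dist(d)
  }
  d1 <- as_d(d1); d2 <- as_d(d2)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices have mismatched site sets")
  n1 <- attr(d1, "Labels"); n2 <- attr(d2, "Labels")
  if (!is.null(n1) && !is.null(n2) && !identical(n1, n2))
    stop("distance matrices have mismatched site ids")
  set.seed(seed)
  # vegan enumerates the full permutation set for small site counts
  # (exact test); silence its advisory messages
  mt <- suppressMessages(
    vegan::mantel(d1, d2, method = "pearson", permutations = n_perm))
  r_obs <- unname(mt$statistic)
  perm <- mt$perm
  p <- if (tail == "greater") (1 + sum(perm >= r_obs)) / (1 + length(perm))
       else (1 + sum(abs(perm) >= abs(r_obs))) / (1 + length(perm))
  structure(list(r = r_obs, p = p, n_perm = length(perm), seed = seed,
                 tail = tail),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%s, %d permutations, seed %d)\n",
              x$r, x$p, x$tail, x$n_perm, x$seed))
  invisible(x)
}

#' Richness and overlap summaries for one or more surveys
#'
#' @param matrices named list of sites x species abundance matrices (one
#'   per survey; column names are species).
#' @return list with `site_richness` (data.frame survey/site/richness),
#'   `survey_totals` (individuals and species per survey),
#'   `relative_abundance` (per survey, species share of total catch), and
#'   `shared_species` (pairwise counts of species present in both surveys).
#' @export
richness_summary <- function(matrices) {
  if (is.null(names(matrices)))
    names(matrices) <- paste0("survey_", seq_along(matrices))
  site_richness <- do.call(rbind, lapply(names(matrices), function(s) {
    m <- as.matrix(matrices[[s]])
    data.frame(survey = s,
               site = if (is.null(rownames(m)))
                 as.character(seq_len(nrow(m))) else rownames(m),
               richness = rowSums(m > 0), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  survey_totals <- do.call(rbind, lapply(names(matrices), function(s) {
    m <- as.matrix(matrices[[s]])
    data.frame(survey = s, individuals = sum(m),
               species = sum(colSums(m) > 0), stringsAsFactors = FALSE)
  }))
  relative_abundance <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    tot <- colSums(m)
    if (sum(tot) > 0) tot / sum(tot) else tot
  })
  nm <- names(matrices)
  shared <- NULL
  if (length(nm) >= 2) {
    pairs <- utils::combn(nm, 2)
    shared <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- as.matrix(matrices[[pairs[1, i]]])
      b <- as.matrix(matrices[[pairs[2, i]]])
      sp_a <- colnames(a)[colSums(a) > 0]
      sp_b <- colnames(b)[colSums(b) > 0]
      data.frame(survey_1 = pairs[1, i], survey_2 = pairs[2, i],
                 shared = length(intersect(sp_a, sp_b)),
                 total = length(union(sp_a, sp_b)),
                 stringsAsFactors = FALSE)
    }))
  }
  list(site_richness = site_richness, survey_totals = survey_totals,
       relative_abundance = relative_abundance, shared_species = shared)
}
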