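#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve with presences as the positive class and
#' background cells as the negative class; ties are credited 0.5. A model
#' with perfect discrimination scores 1; one scoring at random scores 0.5.
#'
#' @param presence_scores numeric scores at presence cells.
#' @param background_scores numeric scores at background cells.
#' @return AUC in \[0,1\].
#' @export
compute_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' The eleven standard suitability thresholds
#'
#' Reconstructs the standard internal threshold set on the logistic scale:
#' three fixed cumulative values (1, 5, 10 percent of raw probability mass),
#' minimum training presence, 10th-percentile training presence, equal
#' training sensitivity and specificity, maximum training
#' sensitivity-plus-specificity, equal test sensitivity and specificity,
#' maximum test sensitivity-plus-specificity, a balance rule trading
#' training omission against predicted area and cumulative value, and an
#' equate-entropy rule (predicted area whose log equals the entropy of the
#' raw distribution).
#'
#' @param surface a `suitability_surface`.
#' @param train_cells,test_cells presence cell ids of the two partitions.
#' @return data.frame with `name` and logistic `value` per threshold.
#' @export
omission_thresholds <- function(surface, train_cells, test_cells) {
  bg <- surface$background_cells
  raw <- surface$raw[bg]
  lgt <- surface$logistic[bg]
  o <- order(raw)
  cum <- cumsum(raw[o]) * 100          # cumulative % of probability mass
  cum_thresh <- function(c) {
    i <- which(cum >= c)[1]
    if (is.na(i)) max(lgt) else lgt[o][i]
  }
  tr <- surface$logistic[train_cells]
  te <- surface$logistic[test_cells]
  sens_spec <- function(pres, crit = c("equal", "max")) {
    crit <- match.arg(crit)
    cand <- sort(unique(c(pres, stats::quantile(lgt, (0:20) / 20,
                                                names = FALSE))))
    sens <- vapply(cand, function(t) mean(pres >= t), numeric(1))
    spec <- vapply(cand, function(t) mean(lgt < t), numeric(1))
    if (crit == "equal") cand[which.min(abs(sens - spec))]
    else cand[which.max(sens + spec)]
  }
  balance <- function() {
    cand <- sort(unique(tr))
    score <- vapply(cand, function(t) {
      om <- mean(tr < t)
      area <- mean(lgt >= t)
      cv <- 100 * sum(raw[lgt < t])
      6 * om + 0.04 * cv + 1.6 * area
    }, numeric(1))
    cand[which.min(score)]
  }
  equate_entropy <- function() {
    cand <- sort(unique(lgt))
    n_above <- vapply(cand, function(t) sum(lgt >= t), numeric(1))
    cand[which.min(abs(log(pmax(n_above, 1)) - surface$H))]
  }
  data.frame(
    name = c("fixed_cumulative_1", "fixed_cumulative_5",
             "fixed_cumulative_10", "min_training_presence",
             "p10_training_presence", "equal_train_sens_spec",
             "max_train_sens_spec", "equal_test_sens_spec",
             "max_test_sens_spec", "balance", "equate_entropy"),
    value = c(cum_thresh(1), cum_thresh(5), cum_thresh(10),
              min(tr), stats::quantile(tr, 0.1, names = FALSE),
              sens_spec(tr, "equal"), sens_spec(tr, "max"),
              sens_spec(te, "equal"), sens_spec(te, "max"),
              balance(), equate_entropy()),
    stringsAsFactors = FALSE)
}

#' Binomial omission tests at a set of thresholds
#'
#' For each threshold t and each partition (train, test): the omission rate
#' is the fraction of that partition's presences scoring below t; the
#' fractional predicted area a is the share of background cells scoring at
#' or above t; and the one-sided p-value is the exact binomial upper tail
#' P(X >= k) for X ~ Binomial(n, a), where k presences out of n score at or
#' above t. Small p indicates prediction better than random at that
#' threshold.
#'
#' @param surface a `suitability_surface`.
#' @param train_cells,test_cells presence cell ids per partition.
#' @param thresholds optional data.frame (`name`, `value`); defaults to
#'   [omission_thresholds()].
#' @return data.frame of class `omission_tests`: threshold name and value,
#'   partition, omission rate, fractional predicted area, p.
#' @export
binomial_omission_tests <- function(surface, train_cells, test_cells,
                                    thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- omission_thresholds(surface, train_cells, test_cells)
  bg <- surface$logistic[surface$background_cells]
  one <- function(part_name, pres) {
    n <- length(pres)
    do.call(rbind, lapply(seq_len(nrow(thresholds)), function(i) {
      t <- thresholds$value[i]
      a <- mean(bg >= t)
      k <- sum(pres >= t)
      p <- stats::pbinom(k - 1, n, a, lower.tail = FALSE)
      data.frame(threshold = thresholds$name[i], value = t,
                 partition = part_name, omission = 1 - k / n,
                 area = a, p = p, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one("train", surface$logistic[train_cells]),
               one("test", surface$logistic[test_cells]))
  class(out) <- c("omission_tests", "data.frame")
  out
}

#' Summarize an ensemble into a validation report
#'
#' @param ensemble a `replicate_ensemble`.
#' @return a `validation_report`: mean train/test AUC over replicates, the
#'   relative train/test AUC gap, and all omission tests across replicates.
#' @export
validation_report <- function(ensemble) {
  train_auc <- vapply(ensemble$replicates, `[[`, numeric(1), "train_auc")
  test_auc <- vapply(ensemble$replicates, `[[`, numeric(1), "test_auc")
  omission <- do.call(rbind, lapply(seq_along(ensemble$replicates),
    function(i) cbind(replicate = i, ensemble$replicates[[i]]$omission)))
  mtr <- mean(train_auc); mte <- mean(test_auc)
  structure(list(species_id = ensemble$species_id,
                 mean_train_auc = mtr, mean_test_auc = mte,
                 auc_gap = abs(mtr - mte) / mtr,
                 train_auc = train_auc, test_auc = test_auc,
                 omission = omission, n_rep = ensemble$n_rep),
            class = "validation_report")
}

#' Apply the three-criterion model acceptance rule
#'
#' A species model is considered reliable and retained for modeled-community
#' construction only if (i) its average test AUC over the replicates exceeds
#' `auc_min`, (ii) every internal training and test binomial occurrence
#' omission analysis across all replicates has p below `p_max`, and (iii)
#' the difference between average test and training AUC is below `gap_max`
#' (relative to the training AUC by default; set `gap_relative = FALSE` for
#' an absolute-difference reading).
#'
#' @param report a [validation_report()].
#' @param auc_min criterion (i) floor on mean test AUC (default 0.9).
#' @param p_max criterion (ii) ceiling on every omission p (default 0.05).
#' @param gap_max criterion (iii) ceiling on the train/test AUC difference
#'   (default 0.05, i.e. five percent).
#' @param gap_relative interpret the gap relative to mean training AUC
#'   (default TRUE).
#' @param all_tests criterion (ii) strict reading: demand p < p_max in every
#'   single test (default TRUE); FALSE requires it of the median p instead.
#' @return an `acceptance_decision`: `accepted` plus per-criterion verdicts
#'   and the computed quantities.
#' @export
evaluate_acceptance <- function(report, auc_min = 0.9, p_max = 0.05,
                                gap_max = 0.05, gap_relative = TRUE,
                                all_tests = TRUE) {
  gap <- abs(report$mean_train_auc - report$mean_test_auc)
  if (gap_relative) gap <- gap / report$mean_train_auc
  p_worst <- max(report$omission$p)
  crit_i <- report$mean_test_auc > auc_min
  crit_ii <- if (all_tests) p_worst < p_max
             else stats::median(report$omission$p) < p_max
  crit_iii <- gap < gap_max
  structure(list(species_id = report$species_id,
                 accepted = crit_i && crit_ii && crit_iii,
                 criterion_i = crit_i, criterion_ii = crit_ii,
                 criterion_iii = crit_iii,
                 mean_test_auc = report$mean_test_auc,
                 mean_train_auc = report$mean_train_auc,
                 worst_omission_p = p_worst, auc_gap = gap),
            class = "acceptance_decision")
}

#' @export
print.acceptance_decision <- function(x, ...) {
  cat(sprintf(
    "acceptance_decision [%s]: %s (i) AUC %.4f %s | (ii) worst p %.3g %s | (iii) gap %.3f %s\n",
    x$species_id, if (x$accepted) "ACCEPTED" else "REJECTED",
    x$mean_test_auc, if (x$criterion_i) "ok" else "FAIL",
    x$worst_omission_p, if (x$criterion_ii) "ok" else "FAIL",
    x$auc_gap, if (x$criterion_iii) "ok" else "FAIL"))
  invisible(x)
}

#' Aggregate expert rankings of candidate models
#'
#' Experts independently rank each candidate variable-set/extent combination
#' on a 1 (poor) to 5 (excellent) scale; rankings are averaged per candidate
#' and the `top_k` candidates by mean rank are selected. Ties are broken
#' deterministically by lexicographic candidate id, and a tie at the
#' selection boundary is flagged in the output.
#'
#' @param table numeric matrix, experts x candidates (column names are
#'   candidate ids), entries in \[1,5\].
#' @param top_k number of variable sets to carry forward (default 2).
#' @return list with `selected` candidate ids, `mean_ranks` (named, sorted
#'   descending), and `tied` flag.
#' @export
aggregate_expert_ranks <- function(table, top_k = 2L) {
  table <- as.matrix(table)
  if (is.null(colnames(table)))
    colnames(table) <- as.character(seq_len(ncol(table)))
  if (any(is.na(table))) stop("empty expert rankings are not allowed")
  if (any(table < 1 | table > 5)) stop("ranks must lie in [1, 5]")
  means <- colMeans(table)
  means <- means[order(-means, names(means))]
  k <- min(top_k, length(means))
  selected <- names(means)[seq_len(k)]
  tied <- k < length(means) && means[k] == means[k + 1]
  list(selected = selected, mean_ranks = means, tied = tied)
}

#' Pick the best candidate model for a species
#'
#' Argmax of mean test AUC over candidate validation reports (one per
#' variable set); exact ties go to the lexicographically lower set id and
#' are flagged.
#'
#' @param candidates named list of [validation_report()]s (names are
#'   variable-set ids) or a named numeric vector of mean test AUCs.
#' @return list with `set_id`, `auc`, `tied`.
#' @export
select_best_model_per_species <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate models")
  aucs <- if (is.numeric(candidates)) candidates
  else vapply(candidates, `[[`, numeric(1), "mean_test_auc")
  if (is.null(names(aucs))) names(aucs) <- as.character(seq_along(aucs))
  best <- max(aucs)
  hits <- sort(names(aucs)[aucs == best])
  list(set_id = hits[1], auc = unname(best), tied = length(hits) > 1)
}
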