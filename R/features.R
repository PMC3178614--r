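#' Expand environmental layers into a maxent feature matrix
#'
#' Builds the feature system used by the maximum-entropy model: continuous
#' layers are min-max scaled to \[0,1\] over the background (the valid cells
#' of the stack) and expanded into linear, quadratic, product, hinge and
#' threshold features; categorical layers expand into one 0/1 indicator per
#' declared category. With `classes = "auto"` the feature classes enabled
#' follow the sample-size tiers of the standard maxent defaults:
#' fewer than 10 presences gives linear only; 10-14 adds quadratic; 15-79
#' adds hinge; 80 or more adds product and threshold.
#'
#' @param stack a `layer_stack`.
#' @param n_presence number of presence records the model will be trained
#'   on; drives tier selection under `classes = "auto"`.
#' @param classes `"auto"` or a character subset of
#'   `c("linear","quadratic","product","hinge","threshold")`.
#' @param n_hinge number of interior knots per layer and orientation for
#'   hinge features (default 8).
#' @param n_threshold number of interior knots per layer for threshold
#'   features (default 8).
#' @return a `feature_matrix`: list with `M` (cells x features, rows are the
#'   stack's valid cells), `cell_ids` (grid cell id of each row),
#'   `descriptors` (per-feature source layer, class, knot/category), and the
#'   scaling used.
#' @export
expand_features <- function(stack, n_presence, classes = "auto",
                            n_hinge = 8L, n_threshold = 8L) {
  if (sum(stack$valid) == 0)
    stop("layer stack has no valid cells; cannot expand features")
  if (identical(classes, "auto")) classes <- feature_tier(n_presence)
  ok <- c("linear", "quadratic", "product", "hinge", "threshold")
  if (length(bad <- setdiff(classes, ok)))
    stop("unknown feature class: ", paste(bad, collapse = ", "))
  cell_ids <- which(stack$valid)
  cols <- list(); desc <- list(); scaling <- list()
  zs <- list()  # scaled continuous layers, for products
  for (l in stack$layers) {
    v <- l$values[cell_ids]
    if (l$kind == "categorical") {
      for (cat in l$categories) {
        cols[[length(cols) + 1L]] <- as.numeric(v == cat)
        desc[[length(desc) + 1L]] <- list(layer = l$name, class = "category",
                                          param = cat)
      }
      next
    }
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("constant layer '", l$name, "' contributes no features")
      next
    }
    z <- (v - rng[1]) / diff(rng)
    scaling[[l$name]] <- rng
    zs[[l$name]] <- z
    if ("linear" %in% classes) {
      cols[[length(cols) + 1L]] <- z
      desc[[length(desc) + 1L]] <- list(layer = l$name, class = "linear",
                                        param = NA)
    }
    if ("quadratic" %in% classes) {
      cols[[length(cols) + 1L]] <- z^2
      desc[[length(desc) + 1L]] <- list(layer = l$name, class = "quadratic",
                                        param = NA)
    }
    if ("hinge" %in% classes && n_hinge > 0) {
      knots <- seq_len(n_hinge) / (n_hinge + 1)
      for (k in knots) {
        cols[[length(cols) + 1L]] <- pmax(0, z - k) / (1 - k)
        desc[[length(desc) + 1L]] <- list(layer = l$name, class = "hinge",
                                          param = k)
        cols[[length(cols) + 1L]] <- pmax(0, k - z) / k
        desc[[length(desc) + 1L]] <- list(layer = l$name,
                                          class = "hinge_reverse", param = k)
      }
    }
    if ("threshold" %in% classes && n_threshold > 0) {
      knots <- seq_len(n_threshold) / (n_threshold + 1)
      for (k in knots) {
        cols[[length(cols) + 1L]] <- as.numeric(z > k)
        desc[[length(desc) + 1L]] <- list(layer = l$name, class = "threshold",
                                          param = k)
      }
    }
  }
  if ("product" %in% classes && length(zs) >= 2) {
    nm <- names(zs)
    for (i in seq_len(length(zs) - 1)) for (j in seq(i + 1, length(zs))) {
      cols[[length(cols) + 1L]] <- zs[[i]] * zs[[j]]
      desc[[length(desc) + 1L]] <- list(layer = paste(nm[i], nm[j], sep = "*"),
                                        class = "product", param = NA)
    }
  }
  M <- if (length(cols)) do.call(cbind, cols)
       else matrix(0, nrow = length(cell_ids), ncol = 0)
  descriptors <- do.call(rbind, lapply(desc, function(d)
    data.frame(layer = d$layer, class = d$class, param = d$param,
               stringsAsFactors = FALSE)))
  if (is.null(descriptors))
    descriptors <- data.frame(layer = character(0), class = character(0),
                              param = numeric(0))
  colnames(M) <- if (nrow(descriptors))
    make.unique(paste(descriptors$layer, descriptors$class,
                      ifelse(is.na(descriptors$param), "",
                             signif(descriptors$param, 3)), sep = "."))
  else character(0)
  structure(list(M = M, cell_ids = cell_ids, descriptors = descriptors,
                 grid = stack$grid, scaling = scaling, classes = classes),
            class = "feature_matrix")
}

#' Feature-class tier for a given presence sample size
#'
#' @param n_presence presence sample size.
#' @return character vector of enabled feature classes.
#' @export
feature_tier <- function(n_presence) {
  if (n_presence < 10) "linear"
  else if (n_presence < 15) c("linear", "quadratic")
  else if (n_presence < 80) c("linear", "quadratic", "hinge")
  else c("linear", "quadratic", "product", "hinge", "threshold")
}

# rows of the feature matrix for a set of grid cell ids
feature_rows <- function(features, cells) {
  idx <- match(cells, features$cell_ids)
  if (anyNA(idx))
    stop(sum(is.na(idx)), " cell(s) fall outside the stack's valid cells")
  idx
}
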