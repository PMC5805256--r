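#' Extract the per-leaf feature vector
#'
#' Runs [analyze_leaf()] and assembles the species-identification features:
#' lobe and sinus counts, apex and base type and angle, the Centroid Contour
#' Gradient vectors of both tips, margin class, ripples ratio and tooth
#' count. Stage failures are recorded in \code{errors} and leave their
#' fields \code{NA} (the vector is flagged \code{incomplete}), never
#' silently filled.
#'
#' @param image image input accepted by [analyze_leaf()].
#' @param config a [leaf_config()].
#' @param species_label optional known species label to attach.
#' @return Object of class \code{leaf_features}.
#' @export
extract_features <- function(image, config = leaf_config(),
                             species_label = NA_character_) {
  an <- analyze_leaf(image, config)
  ng <- 90 / config$ccg_interval
  grad_or_na <- function(cl) {
    if (is.null(cl$ccg)) rep(NA_real_, ng) else cl$ccg$gradients
  }
  errors <- c(apex = an$apex$error, base = an$base$error)
  structure(list(
    lobes = an$counts$lobes,
    sinuses = an$counts$sinuses,
    apex_type = an$apex$label,
    base_type = an$base$label,
    apex_angle = an$apex$apex_angle,
    base_angle = an$base$base_angle,
    ccg_apex = grad_or_na(an$apex),
    ccg_base = grad_or_na(an$base),
    margin_class = an$margin$margin_class,
    ripples_ratio = an$margin$ripples_ratio,
    teeth_count = length(an$margin$teeth_peaks),
    species_label = species_label,
    incomplete = length(errors) > 0 || anyNA(c(an$apex$label, an$base$label)),
    errors = errors
  ), class = "leaf_features")
}

#' Feature list to data frame
#'
#' Flattens a list of \code{leaf_features} into a data frame (CCG vectors
#' become \code{ccg_apex_1 ...} columns), suitable for CSV export.
#'
#' @param features list of \code{leaf_features}.
#' @return A data.frame, one row per leaf.
#' @export
features_to_df <- function(features) {
  if (inherits(features, "leaf_features")) features <- list(features)
  rows <- lapply(features, function(f) {
    row <- data.frame(lobes = f$lobes, sinuses = f$sinuses,
                      apex_type = f$apex_type, base_type = f$base_type,
                      apex_angle = f$apex_angle, base_angle = f$base_angle,
                      margin_class = f$margin_class,
                      ripples_ratio = f$ripples_ratio,
                      teeth_count = f$teeth_count,
                      species_label = f$species_label,
                      incomplete = f$incomplete,
                      stringsAsFactors = FALSE)
    for (i in seq_along(f$ccg_apex)) row[[paste0("ccg_apex_", i)]] <- f$ccg_apex[i]
    for (i in seq_along(f$ccg_base)) row[[paste0("ccg_base_", i)]] <- f$ccg_base[i]
    row
  })
  do.call(rbind, rows)
}

# Mixed distance between two feature vectors given train-set scaling stats.
feature_distance <- function(a, b, stats) {
  d <- 0
  for (f in names(stats$num)) {
    s <- stats$num[[f]]
    if (s$sd > 0 && is.finite(a[[f]]) && is.finite(b[[f]]))
      d <- d + abs((a[[f]] - s$mean) / s$sd - (b[[f]] - s$mean) / s$sd)
  }
  for (f in c("ccg_apex", "ccg_base")) {
    va <- a[[f]]; vb <- b[[f]]
    if (!anyNA(va) && !anyNA(vb) && stats$ccg_sd > 0)
      d <- d + sqrt(sum((va - vb)^2)) / stats$ccg_sd
  }
  for (f in c("apex_type", "base_type", "margin_class")) {
    da <- a[[f]]; db <- b[[f]]
    if (!is.na(da) && !is.na(db)) d <- d + (da != db)
  }
  d
}

#' Nearest neighbour species identification
#'
#' Matches a query feature vector against a labelled reference set under a
#' mixed distance: z-scored numeric features (scaled on the reference set),
#' Euclidean distance between Centroid Contour Gradient vectors, and a 0/1
#' mismatch for each categorical feature. Ties resolve to the earliest
#' reference record.
#'
#' @param train list of labelled \code{leaf_features} (the reference set).
#' @param query a \code{leaf_features}.
#' @param k number of neighbours (majority vote; 1 by default).
#' @return The predicted species label (character).
#' @export
knn_classify <- function(train, query, k = 1L) {
  if (!length(train)) stop("no reference set")
  stats <- knn_stats(train)
  d <- vapply(train, function(t) feature_distance(query, t, stats), numeric(1))
  o <- order(d)
  labs <- vapply(train[o[seq_len(min(k, length(train)))]],
                 function(t) t$species_label, character(1))
  mode_first(labs)
}

# Scaling statistics of the numeric features over the train set.
knn_stats <- function(train) {
  numf <- c("lobes", "sinuses", "apex_angle", "base_angle",
            "ripples_ratio", "teeth_count")
  num <- lapply(setNames(numf, numf), function(f) {
    v <- vapply(train, function(t) as.numeric(t[[f]]), numeric(1))
    v <- v[is.finite(v)]
    list(mean = if (length(v)) mean(v) else 0,
         sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  ccg <- unlist(lapply(train, function(t) c(t$ccg_apex, t$ccg_base)))
  ccg <- ccg[is.finite(ccg)]
  list(num = num, ccg_sd = if (length(ccg) > 1) stats::sd(ccg) else 0)
}

#' Identification accuracy
#'
#' Fraction of predictions matching the true labels.
#'
#' @param predictions character vector of predicted labels.
#' @param truth character vector of true labels, same length.
#' @return Accuracy in \code{[0, 1]}.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("misaligned evaluation")
  if (!length(truth)) return(NA_real_)
  mean(predictions == truth)
}

#' Evaluate nearest neighbour identification on a labelled split
#'
#' @param train,test lists of labelled \code{leaf_features}.
#' @param k neighbours for [knn_classify()].
#' @return List with \code{accuracy}, \code{predictions}, \code{truth},
#'   \code{confusion} (table).
#' @export
evaluate_knn <- function(train, test, k = 1L) {
  truth <- vapply(test, function(t) t$species_label, character(1))
  unknown <- setdiff(truth, vapply(train, function(t) t$species_label, character(1)))
  if (length(unknown)) stop("label mismatch: test species missing from train: ",
                            paste(unknown, collapse = ", "))
  preds <- vapply(test, function(q) knn_classify(train, q, k), character(1))
  list(accuracy = accuracy(preds, truth), predictions = preds, truth = truth,
       confusion = table(truth = truth, predicted = preds))
}
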