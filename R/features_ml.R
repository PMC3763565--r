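#' Arpeggio MDS: principal-component embedding of spectral densities
#'
#' Each spectral density is low-pass filtered (scales below
#' `cutoff_scale` bp zeroed, suppressing read-scale noise), its real part
#' taken (the transform of a true autocorrelation should be real; the
#' negligible numerical imaginary part is discarded), and PCA applied to
#' the resulting sample-by-frequency matrix. Six leading components
#' suffice to describe large heterogeneous collections, hence `k = 6` by
#' default.
#'
#' @param spectra list of [spectral_density()] objects of equal length.
#' @param k number of leading components to keep (default 6); truncated
#'   with a warning if it exceeds `samples - 1`.
#' @param cutoff_scale low-pass cutoff in bp (default 40).
#' @return An `mds_embedding`: `sample_ids`, `coordinates` (samples x k),
#'   `explained_variance_fraction` per kept component (non-increasing,
#'   zeros when the panel has no variance).
#' @export
arpeggio_mds <- function(spectra, k = 6, cutoff_scale = 40) {
  if (length(spectra) < 2) stop("need at least 2 samples")
  lens <- vapply(spectra, function(s) s$n_bins, numeric(1))
  if (length(unique(lens)) != 1) stop("spectra have unequal lengths")
  mat <- t(vapply(spectra,
                  function(s) Re(low_pass(s, cutoff_scale)$values),
                  numeric(lens[1])))
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  n <- nrow(mat)
  if (k > n - 1) {
    warning("k truncated from ", k, " to ", n - 1)
    k <- n - 1
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  kk <- min(k, ncol(pc$x))
  coords <- matrix(0, n, k, dimnames = list(ids, paste0("PC", seq_len(k))))
  coords[, seq_len(kk)] <- pc$x[, seq_len(kk), drop = FALSE]
  expl <- numeric(k)
  if (total_var > 0) expl[seq_len(kk)] <- (pc$sdev^2 / total_var)[seq_len(kk)]
  structure(list(sample_ids = ids, coordinates = coords,
                 explained_variance_fraction = expl,
                 cutoff_scale = cutoff_scale),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d samples x %d components (%.1f%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}

.coords_matrix <- function(x, max_dims = 6L) {
  m <- if (inherits(x, "mds_embedding")) x$coordinates else as.matrix(x)
  m[, seq_len(min(ncol(m), max_dims)), drop = FALSE]
}

.db_statistic <- function(coords, labels) {
  labs <- unique(labels)
  cent <- t(vapply(labs, function(l)
    colMeans(coords[labels == l, , drop = FALSE]), numeric(ncol(coords))))
  disp <- vapply(seq_along(labs), function(i) {
    pts <- coords[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(cent[i, ], each = nrow(pts)))^2)))
  }, numeric(1))
  n <- length(labs)
  ratios <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    ratios[i, j] <- if (d == 0) {
      if (disp[i] + disp[j] == 0) 0 else Inf
    } else (disp[i] + disp[j]) / d
  }
  list(db = mean(apply(ratios, 1, max, na.rm = TRUE)),
       centroids = cent, dispersions = disp, labels = labs)
}

#' Davies-Bouldin index of a labelled embedding, with bootstrap p-value
#'
#' Clusters are the class labels; the index is the average over clusters
#' of the worst-case ratio of summed within-cluster mean dispersions to
#' the Euclidean distance between centroids, computed on (up to) the six
#' leading components. Lower means better separated. The p-value is the
#' fraction of label permutations (preserving cluster sizes) whose index
#' is at most the observed one.
#'
#' @param embedding an `mds_embedding` or a numeric coordinate matrix.
#' @param labels per-sample class labels (one and only one per sample).
#' @param n_boot number of label permutations (default 1000).
#' @param seed optional RNG seed for the bootstrap.
#' @return A `clustering_report`: `db_index`, `n_clusters`, `centroids`,
#'   `dispersions`, `p_value`, `infinite` flag (coincident centroids of
#'   non-identical clusters).
#' @export
davies_bouldin <- function(embedding, labels, n_boot = 1000, seed = NULL) {
  coords <- .coords_matrix(embedding)
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    stop("labels length does not match sample count")
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  obs <- .db_statistic(coords, labels)
  p <- NA_real_
  if (n_boot > 0) {
    perm <- .with_seed(seed, vapply(seq_len(n_boot), function(b)
      .db_statistic(coords, sample(labels))$db, numeric(1)))
    p <- mean(perm <= obs$db)
  }
  structure(list(db_index = obs$db, n_clusters = length(obs$labels),
                 cluster_labels = obs$labels, centroids = obs$centroids,
                 dispersions = obs$dispersions, p_value = p,
                 n_boot = n_boot, infinite = !is.finite(obs$db)),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf("clustering_report: DB = %.4f over %d clusters (bootstrap p = %s, n = %d)\n",
              x$db_index, x$n_clusters, format(x$p_value), x$n_boot))
  invisible(x)
}

.distance_matrix <- function(x, distance) {
  if (distance == "precomputed") {
    D <- as.matrix(x)
    if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) ||
        any(abs(diag(D)) > 1e-8))
      stop("precomputed distances must be symmetric with zero diagonal")
    D
  } else {
    as.matrix(stats::dist(.coords_matrix(x)))
  }
}

.balanced_accuracy <- function(truth, predicted, labs) {
  acc <- vapply(labs, function(l) {
    n <- sum(truth == l)
    if (n == 0) NA_real_ else sum(truth == l & predicted == l) / n
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

.knn_confusion <- function(D, labels, keep) {
  labs <- sort(unique(labels))
  conf <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in keep) {
    cand <- setdiff(keep, i)
    j <- cand[which.min(D[i, cand])]
    conf[labels[i], labels[j]] <- conf[labels[i], labels[j]] + 1
  }
  conf
}

#' Leave-one-out k=1 nearest-neighbour classification
#'
#' A 1-nearest-neighbour classifier is evaluated leave-one-out: each
#' sample is assigned the label of its nearest retained neighbour. To
#' avoid replicate leakage, each repetition keeps one sample per
#' replicate group at random; results are accumulated over repetitions.
#' Performance is the balanced accuracy (per-label accuracy averaged over
#' labels); labels with a single sample overall have no valid LOO trainer
#' and are excluded with a warning. Significance is assessed against a
#' random-label null by permutation.
#'
#' @param x an `mds_embedding`, coordinate matrix, or (with
#'   `distance = "precomputed"`) a symmetric distance matrix.
#' @param labels per-sample class labels.
#' @param replicate_groups per-sample replicate-group ids; `NULL` means
#'   every sample is its own group (one deterministic pass).
#' @param n_rep repetitions of the replicate subsampling (default 20;
#'   forced to 1 when groups are trivial).
#' @param n_boot label permutations for the p-value (default 100).
#' @param seed optional RNG seed.
#' @param distance `"euclidean"` (on embedding coordinates) or
#'   `"precomputed"`.
#' @return A `classification_report`: `balanced_accuracy`, accumulated
#'   `confusion` matrix (rows = truth, columns = prediction), `p_value`,
#'   `excluded_labels`.
#' @export
knn_classify <- function(x, labels, replicate_groups = NULL, n_rep = 20,
                         n_boot = 100, seed = NULL,
                         distance = c("euclidean", "precomputed")) {
  distance <- match.arg(distance)
  D <- .distance_matrix(x, distance)
  labels <- as.character(labels)
  n <- nrow(D)
  if (length(labels) != n) stop("labels length does not match sample count")
  if (length(unique(labels)) < 2) stop("need at least 2 labels")
  if (is.null(replicate_groups)) replicate_groups <- as.character(seq_len(n))
  replicate_groups <- as.character(replicate_groups)
  singleton <- names(which(table(labels) == 1))
  if (length(singleton))
    warning("label(s) with a single sample excluded from balanced accuracy: ",
            paste(singleton, collapse = ", "))
  labs <- setdiff(sort(unique(labels)), singleton)
  trivial <- !anyDuplicated(replicate_groups)
  if (trivial) n_rep <- 1
  run <- function(lab_vec) {
    conf <- NULL
    for (r in seq_len(n_rep)) {
      keep <- if (trivial) seq_len(n) else
        vapply(split(seq_len(n), replicate_groups),
               function(ix) if (length(ix) == 1) ix else sample(ix, 1),
               integer(1))
      cf <- .knn_confusion(D, lab_vec, sort(unname(keep)))
      conf <- if (is.null(conf)) cf else conf + cf
    }
    conf
  }
  conf <- .with_seed(seed, run(labels))
  truth_counts <- rowSums(conf)
  ba <- mean(vapply(labs, function(l)
    if (truth_counts[l] > 0) conf[l, l] / truth_counts[l] else NA_real_,
    numeric(1)), na.rm = TRUE)
  p <- NA_real_
  if (n_boot > 0) {
    null_ba <- .with_seed(if (is.null(seed)) NULL else seed + 1L,
      vapply(seq_len(n_boot), function(b) {
        lp <- sample(labels)
        cf <- run(lp)
        tc <- rowSums(cf)
        mean(vapply(labs, function(l)
          if (tc[l] > 0) cf[l, l] / tc[l] else NA_real_, numeric(1)),
          na.rm = TRUE)
      }, numeric(1)))
    p <- mean(null_ba >= ba)
  }
  structure(list(balanced_accuracy = ba, confusion = conf, p_value = p,
                 n_rep = n_rep, n_boot = n_boot,
                 excluded_labels = singleton),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: balanced accuracy %.3f (bootstrap p = %s)\n",
              x$balanced_accuracy, format(x$p_value)))
  invisible(x)
}

.auc_midrank <- function(scores, positive) {
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)  # midranks on ties
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Per-class-variable AUC aggregation over pairwise distances
#'
#' For each anchor sample, other samples with the anchor's class label
#' are positives and the rest negatives (the anchor's own replicates are
#' excluded), and the AUC of ranking by increasing distance is computed.
#' Each of `n_rep` repetitions retains one replicate per group at random;
#' per-sample expected AUC and its sd are averaged within each label, and
#' the medians across labels are reported (robust to outlier labels).
#'
#' @param distances symmetric pairwise distance matrix, zero diagonal.
#' @param labels per-sample class labels.
#' @param replicate_groups per-sample replicate-group ids (`NULL`: each
#'   sample its own group).
#' @param n_rep repetitions of replicate resampling (default 100).
#' @param seed optional RNG seed.
#' @return List with `median_auc`, `median_sd`, `per_label` (data.frame
#'   `label`, `mean_auc`, `mean_sd`), `per_sample`, `excluded_labels`.
#' @export
auc_aggregation <- function(distances, labels, replicate_groups = NULL,
                            n_rep = 100, seed = NULL) {
  D <- .distance_matrix(distances, "precomputed")
  labels <- as.character(labels)
  n <- nrow(D)
  if (length(labels) != n) stop("labels length does not match sample count")
  if (is.null(replicate_groups)) replicate_groups <- as.character(seq_len(n))
  replicate_groups <- as.character(replicate_groups)
  groups <- split(seq_len(n), replicate_groups)
  aucs <- matrix(NA_real_, n, n_rep)
  .with_seed(seed, {
    for (r in seq_len(n_rep)) {
      keep <- vapply(groups, function(ix)
        if (length(ix) == 1) ix else sample(ix, 1), integer(1))
      keep <- sort(unname(keep))
      for (i in seq_len(n)) {
        # anchor's replicates (and the anchor) never enter the ranking
        others <- setdiff(keep, which(replicate_groups == replicate_groups[i]))
        if (!length(others)) next
        pos <- labels[others] == labels[i]
        aucs[i, r] <- .auc_midrank(-D[i, others], pos)
      }
    }
  })
  per_sample <- data.frame(
    sample = seq_len(n), label = labels,
    mean_auc = rowMeans(aucs, na.rm = TRUE),
    sd_auc = apply(aucs, 1, stats::sd, na.rm = TRUE))
  valid <- !is.nan(per_sample$mean_auc)
  excluded <- unique(labels[!valid])
  if (length(excluded))
    warning("label(s) with no non-replicate positives excluded: ",
            paste(excluded, collapse = ", "))
  ps <- per_sample[valid, ]
  per_label <- do.call(rbind, lapply(split(ps, ps$label), function(d)
    data.frame(label = d$label[1], mean_auc = mean(d$mean_auc),
               mean_sd = mean(d$sd_auc, na.rm = TRUE))))
  rownames(per_label) <- NULL
  list(median_auc = stats::median(per_label$mean_auc),
       median_sd = stats::median(per_label$mean_sd),
       per_label = per_label, per_sample = per_sample,
       excluded_labels = excluded)
}

#' Jaccard distance between two peak sets
#'
#' Two peaks overlap if they share at least 1 bp. The overlap count is
#' symmetrized as the average of (peaks of a hitting b) and (peaks of b
#' hitting a) — in one-to-one situations this is the obvious shared-peak
#' count. The total is `|a| + |b| - o` and the distance `1 - o / total`.
#'
#' @param a,b [peak_set()] objects (already merged/non-overlapping).
#' @return A number in `[0, 1]`; 0 for identical sets, 1 for disjoint.
#'   Errors when both sets are empty (undefined distance).
#' @export
jaccard_peak_distance <- function(a, b) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  na <- length(a$intervals); nb <- length(b$intervals)
  if (na + nb == 0) stop("undefined distance: both peak sets are empty")
  oa <- sum(GenomicRanges::countOverlaps(a$intervals, b$intervals,
                                         minoverlap = 1L) > 0)
  ob <- sum(GenomicRanges::countOverlaps(b$intervals, a$intervals,
                                         minoverlap = 1L) > 0)
  o <- (oa + ob) / 2
  total <- na + nb - o
  1 - o / total
}

#' Pairwise distances between spectral densities
#'
#' `1 - Pearson` on low-passed spectral magnitudes (DC excluded) — the
#' inverse-correlation dissimilarity used alongside Euclidean distance on
#' Arpeggio MDS coordinates.
#'
#' @param spectra list of [spectral_density()] objects of equal length.
#' @param cutoff_scale low-pass cutoff in bp (default 40).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
spectral_correlation_distance <- function(spectra, cutoff_scale = 40) {
  mat <- t(vapply(spectra,
                  function(s) Mod(low_pass(s, cutoff_scale)$values)[-1],
                  numeric(spectra[[1]]$n_bins - 1)))
  D <- 1 - stats::cor(t(mat))
  diag(D) <- 0
  dimnames(D) <- list(vapply(spectra, `[[`, character(1), "sample_id"),
                      vapply(spectra, `[[`, character(1), "sample_id"))
  D
}
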