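# Accuracy assessment of a binary (mangrove / non-mangrove) map:
# buffered random-point validation around ground-truth sites, confusion
# matrices, overall accuracy, Cohen's kappa, pairwise two-proportion
# Z comparison of maps, digitizer quality control and survey sample-size
# design.

CLASSES <- c("mangrove", "non-mangrove")

#' Ground-truth site with a circular validation buffer
#'
#' @param x,y site coordinates in metres.
#' @param label observed class, `"mangrove"` or `"non-mangrove"`.
#' @param buffer_radius buffer radius in metres (default 100 m, i.e. a
#'   3.14 ha disc).
#' @return an object of class `ground_truth_site`; its `buffer_area_ha`
#'   field is `pi * r^2 / 1e4`.
#' @export
ground_truth_site <- function(x, y, label, buffer_radius = 100) {
  label <- match.arg(label, CLASSES)
  if (!is.finite(buffer_radius) || buffer_radius <= 0)
    stop("buffer_radius must be positive")
  structure(list(x = x, y = y, label = label,
                 buffer_radius = buffer_radius,
                 buffer_area_ha = pi * buffer_radius^2 / 1e4),
            class = "ground_truth_site")
}

#' Random validation points inside a site buffer
#'
#' Uniform points in the disc of radius `buffer_radius` around the site,
#' each carrying the site's ground-truth label.
#' @param site a `ground_truth_site`.
#' @param n_points number of points (default 500).
#' @param seed optional integer; when supplied the draw is reproducible.
#' @return data frame with columns `x`, `y`, `truth`.
#' @export
sample_validation_points <- function(site, n_points = 500, seed = NULL) {
  stopifnot(inherits(site, "ground_truth_site"), n_points >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- site$buffer_radius * sqrt(runif(n_points))
  th <- runif(n_points, 0, 2 * pi)
  data.frame(x = site$x + r * cos(th), y = site$y + r * sin(th),
             truth = site$label, stringsAsFactors = FALSE)
}

#' Confusion matrix of a map against labelled points
#'
#' Each point is classified by point-in-polygon against the map layer
#' (boundary points count as mangrove) and tallied against its
#' ground-truth label.
#' @param map a `patch_layer` of mapped mangrove patches.
#' @param points data frame with columns `x`, `y`, `truth` (values
#'   `"mangrove"` / `"non-mangrove"`).
#' @return a `confusion_matrix`: 2 x 2 integer table (map class in rows,
#'   truth in columns) with attribute `n`.
#' @export
confusion <- function(map, points) {
  if (!nrow(points)) stop("empty point set")
  if (!all(points$truth %in% CLASSES))
    stop("truth labels must be 'mangrove' or 'non-mangrove'")
  mapped <- ifelse(points_in_layer(cbind(points$x, points$y), map),
                   CLASSES[1L], CLASSES[2L])
  cm <- table(factor(mapped, levels = CLASSES),
              factor(points$truth, levels = CLASSES))
  dimnames(cm) <- list(map = CLASSES, truth = CLASSES)
  structure(unclass(cm), class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#'
#' @param counts 2 x 2 matrix of agreement counts, map class in rows,
#'   truth in columns.
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  dimnames(counts) <- list(map = CLASSES, truth = CLASSES)
  structure(counts, class = "confusion_matrix")
}

#' Overall accuracy of a confusion matrix
#'
#' Proportion of correctly classified sample points, as a percentage.
#' @param cm a `confusion_matrix` (or plain 2 x 2 matrix).
#' @return percentage in \[0, 100\].
#' @export
overall_accuracy <- function(cm) {
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix")
  100 * sum(diag(as.matrix(cm))) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the chance
#' term computed from the matrix marginals.
#' @param cm a `confusion_matrix` (or plain square matrix).
#' @return kappa in \[-1, 1\]; `NA` with a warning when the marginals
#'   are degenerate (chance agreement equals 1).
#' @export
cohens_kappa <- function(cm) {
  m <- as.matrix(cm)
  n <- sum(m)
  if (n < 1) stop("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate single-class marginals: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Two-proportion Z comparison of map accuracies
#'
#' Difference of the two correct-classification proportions over the
#' pooled standard error:
#' `Z = (x1/n1 - x2/n2) / sqrt(rho (1 - rho) (1/n1 + 1/n2))` with
#' `rho = (x1 + x2) / (n1 + n2)`. `|Z| >= 1.96` flags a significant
#' difference at the 5% level.
#' @param x1,x2 numbers of correctly classified points (may be
#'   non-integer when derived from printed accuracy percentages).
#' @param n1,n2 total numbers of validation points.
#' @return an object of class `z_comparison` with fields `x1`, `n1`,
#'   `x2`, `n2`, `p1`, `p2`, `rho`, `z`, `significant`.
#' @export
z_compare <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  rho <- (x1 + x2) / (n1 + n2)
  if (rho <= 0 || rho >= 1)
    stop("degenerate pooled proportion: rho must lie strictly in (0, 1)")
  z <- (x1 / n1 - x2 / n2) / sqrt(rho * (1 - rho) * (1 / n1 + 1 / n2))
  structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                 p1 = x1 / n1, p2 = x2 / n2, rho = rho, z = z,
                 significant = abs(z) >= 1.96),
            class = "z_comparison")
}

#' @export
print.z_comparison <- function(x, ...) {
  cat(sprintf("Z = %.3f (p1 = %.3f, p2 = %.3f, pooled rho = %.3f)%s\n",
              x$z, x$p1, x$p2, x$rho,
              if (x$significant) "  |Z| >= 1.96: significant" else ""))
  invisible(x)
}

#' Z comparison from accuracy percentages
#'
#' Convenience wrapper converting printed overall accuracies (percent)
#' to correct-point counts at the stated validation sample sizes.
#' @param acc1,acc2 overall accuracies in percent.
#' @param n1,n2 validation sample sizes (default 500).
#' @return a `z_comparison`.
#' @export
z_compare_accuracy <- function(acc1, acc2, n1 = 500, n2 = 500) {
  z_compare(acc1 / 100 * n1, n1, acc2 / 100 * n2, n2)
}

#' Digitizer quality control of one polygon
#'
#' Fraction of the candidate polygon's exterior perimeter lying within
#' `tol` metres of the reference patch outline; the polygon is rated
#' accurate when at least half its perimeter coincides.
#' @param candidate,reference `patch_polygon` objects (digitized vs
#'   actual patch outline).
#' @param tol coincidence tolerance in metres (default 5).
#' @param step arc-length sampling step along the candidate boundary
#'   (default `tol / 10`).
#' @return list with `fraction` (coinciding perimeter fraction) and
#'   `accurate` (`fraction >= 0.5`).
#' @export
digitizer_qa <- function(candidate, reference, tol = 5, step = tol / 10) {
  stopifnot(tol > 0, step > 0)
  ring <- rbind(candidate$exterior, candidate$exterior[1L, ])
  seg <- cbind(diff(ring[, 1L]), diff(ring[, 2L]))
  len <- sqrt(rowSums(seg^2))
  # midpoints of equal-length sub-segments along each edge
  pts <- do.call(rbind, lapply(which(len > 0), function(i) {
    k <- max(1L, ceiling(len[i] / step))
    t <- (seq_len(k) - 0.5) / k
    cbind(ring[i, 1L] + t * seg[i, 1L], ring[i, 2L] + t * seg[i, 2L])
  }))
  w <- unlist(lapply(which(len > 0), function(i) {
    k <- max(1L, ceiling(len[i] / step))
    rep(len[i] / k, k)
  }))
  refring <- rbind(reference$exterior, reference$exterior[1L, ])
  d <- cpp_point_polyline_dist(pts, refring)
  fraction <- sum(w[d <= tol]) / sum(w)
  list(fraction = fraction, accurate = fraction >= 0.5)
}

#' Digitization error rate per stratum
#'
#' `100 * inaccurate / sampled` per stratum (island), from quality-
#' control flags or counts.
#' @param sampled integer vector of sampled polygon counts per stratum.
#' @param inaccurate integer vector of inaccurate counts per stratum.
#' @param stratum optional stratum labels.
#' @return data frame with columns `stratum`, `sampled`, `inaccurate`,
#'   `error_pct`.
#' @export
qa_error_rate <- function(sampled, inaccurate, stratum = names(sampled)) {
  stopifnot(length(sampled) == length(inaccurate), all(sampled >= 1),
            all(inaccurate >= 0), all(inaccurate <= sampled))
  if (is.null(stratum)) stratum <- as.character(seq_along(sampled))
  data.frame(stratum = stratum, sampled = as.integer(sampled),
             inaccurate = as.integer(inaccurate),
             error_pct = 100 * inaccurate / sampled,
             stringsAsFactors = FALSE)
}

#' Survey sample size (Cochran with finite-population correction)
#'
#' `n0 = z^2 * 0.25 / margin^2`, corrected as
#' `n = n0 / (1 + (n0 - 1) / population)` and rounded up. The default
#' `z = 2.58` is the conventional two-decimal value for 99% confidence;
#' pass `z = 2.576` for the finer tabulation, or `z = 1.96` for 95%.
#' @param population number of polygons in the frame.
#' @param margin margin of error as a fraction (default 0.05).
#' @param z normal quantile for the confidence level (default 2.58).
#' @return integer sample size.
#' @export
survey_sample_size <- function(population, margin = 0.05, z = 2.58) {
  stopifnot(population >= 1, margin > 0, margin < 1, z > 0)
  n0 <- z^2 * 0.25 / margin^2
  n <- n0 / (1 + (n0 - 1) / population)
  as.integer(min(population, ceiling(n)))
}

#' Fraction-of-population sample size
#'
#' Plain proportional sampling, e.g. an 8% stratified random sample.
#' @param population number of polygons.
#' @param fraction sampling fraction in (0, 1\].
#' @return integer sample size (rounded up).
#' @export
fraction_sample_size <- function(population, fraction) {
  stopifnot(population >= 1, fraction > 0, fraction <= 1)
  as.integer(ceiling(population * fraction))
}

#' Repeated map validation against ground-truth sites
#'
#' Runs the buffered random-point validation `repeats` times with fresh
#' seeds and reports the per-repeat and mean accuracy and kappa; the
#' repetition guards the assessment against a single unlucky point draw.
#' @param map a `patch_layer`.
#' @param sites list of `ground_truth_site` objects.
#' @param n_points points per site buffer per repeat (default 500).
#' @param repeats number of repeats (default 3).
#' @param seed integer seed for the first repeat; subsequent repeats use
#'   `seed + 1`, `seed + 2`, ...
#' @return list with `per_repeat` (data frame of `accuracy_pct`,
#'   `kappa`), `mean_accuracy_pct`, `mean_kappa`, and the pooled
#'   `confusion` of the last repeat.
#' @export
validate_map <- function(map, sites, n_points = 500, repeats = 3, seed = 1) {
  stopifnot(length(sites) >= 1, repeats >= 1)
  acc <- kap <- numeric(repeats)
  cm <- NULL
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    pts <- do.call(rbind, lapply(sites, sample_validation_points,
                                 n_points = n_points))
    cm <- confusion(map, pts)
    acc[r] <- overall_accuracy(cm)
    kap[r] <- cohens_kappa(cm)
  }
  list(per_repeat = data.frame(repeat_ = seq_len(repeats),
                               accuracy_pct = acc, kappa = kap),
       mean_accuracy_pct = mean(acc), mean_kappa = mean(kap),
       confusion = cm)
}
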