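## Wing-colour morphometrics: disc averaging, colour spaces, ordination and
## a from-scratch permutational multivariate ANOVA.

#' Convert RGB channels to HSV
#'
#' Standard hexcone conversion (the colour-picker convention): hue in
#' degrees \[0, 360), saturation and value in \[0, 1\]. Grey inputs have
#' undefined hue, reported as 0 with saturation 0. Wraps the base
#' [grDevices::rgb2hsv()] conversion; channels may be fractional (e.g. disc
#' means).
#'
#' @param r,g,b numeric vectors of channel values in \[0, 255\].
#' @return Matrix with columns `H`, `S`, `V`.
#' @export
#' @examples
#' rgb_to_hsv(255, 0, 0)  # H 0, S 1, V 1
rgb_to_hsv <- function(r, g, b) {
  x <- cbind(r, g, b)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 255))
    stop("RGB channels must lie in [0, 255]")
  hsv <- t(grDevices::rgb2hsv(t(x), maxColorValue = 255))
  out <- cbind(H = hsv[, 1] * 360, S = hsv[, 2], V = hsv[, 3])
  out[out[, "H"] >= 360, "H"] <- 0
  out
}

#' Convert HSV back to RGB channels
#'
#' Inverse hexcone conversion, returning continuous channels on \[0, 255\]
#' (not rounded to integers), so that `rgb_to_hsv()` round-trips exactly.
#'
#' @param h hue in degrees \[0, 360); `s`, `v` in \[0, 1\].
#' @param s,v saturation and value.
#' @return Matrix with columns `R`, `G`, `B`.
#' @export
hsv_to_rgb <- function(h, s, v) {
  if (any(h < 0 | h >= 360) || any(s < 0 | s > 1) || any(v < 0 | v > 1))
    stop("need H in [0, 360), S and V in [0, 1]")
  hh <- h / 60
  i <- floor(hh)
  f <- hh - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(R = r * 255, G = g * 255, B = b * 255)
}

#' Average disc measurements into per-specimen colour profiles
#'
#' Wing colour is measured on several uniform discs per specimen (three per
#' wing in the standard protocol); the per-specimen profile is the
#' arithmetic channel mean over discs, with HSV derived from the mean RGB.
#'
#' @param measurements data frame with columns `specimen_id`, `disc`, `R`,
#'   `G`, `B` and optionally `group` and `substrate` (constant within
#'   specimen).
#' @return Data frame of class `colour_profiles`: one row per specimen with
#'   columns `specimen_id`, `R`, `G`, `B`, `H`, `S`, `V` and any `group` /
#'   `substrate` labels carried through.
#' @export
average_discs <- function(measurements) {
  need <- c("specimen_id", "R", "G", "B")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (ch in c("R", "G", "B")) {
    v <- measurements[[ch]]
    if (any(!is.finite(v)))
      stop("missing ", ch, " channel value")
    if (any(v < 0 | v > 255))
      stop(ch, " channel out of [0, 255]")
  }
  sp <- factor(measurements$specimen_id,
               levels = unique(measurements$specimen_id))
  prof <- data.frame(
    specimen_id = levels(sp),
    R = as.numeric(tapply(measurements$R, sp, mean)),
    G = as.numeric(tapply(measurements$G, sp, mean)),
    B = as.numeric(tapply(measurements$B, sp, mean)),
    stringsAsFactors = FALSE)
  prof <- cbind(prof, rgb_to_hsv(prof$R, prof$G, prof$B))
  for (extra in c("group", "substrate")) {
    if (extra %in% names(measurements)) {
      val <- tapply(as.character(measurements[[extra]]), sp,
                    function(v) {
                      u <- unique(v)
                      if (length(u) > 1L)
                        stop("inconsistent '", extra, "' within a specimen")
                      u
                    })
      prof[[extra]] <- as.character(val)
    }
  }
  rownames(prof) <- NULL
  class(prof) <- c("colour_profiles", "data.frame")
  prof
}

#' Euclidean colour distance matrix
#'
#' @param profiles a `colour_profiles` data frame.
#' @param space `"RGB"` (default, the headline analysis) or `"HSV"`. Note
#'   hue is treated as a linear coordinate in HSV space; profiles spanning
#'   the 0/360 wrap-around should use RGB.
#' @return A [stats::dist] object labelled by specimen ID.
#' @export
colour_distance_matrix <- function(profiles, space = c("RGB", "HSV")) {
  space <- match.arg(space)
  if (nrow(profiles) < 2L) stop("need at least two profiles")
  cols <- if (space == "RGB") c("R", "G", "B") else c("H", "S", "V")
  x <- as.matrix(profiles[, cols])
  rownames(x) <- profiles$specimen_id
  stats::dist(x)
}

#' Non-metric multidimensional scaling of a colour distance matrix
#'
#' Monotone-regression NMDS via [vegan::monoMDS()], run from a metric
#' (principal-coordinates) start plus `n_starts - 1` seeded random starts;
#' the configuration with the lowest Kruskal stress-1 is kept. Coordinates
#' are centred.
#'
#' @param d a [stats::dist] object (at least three points).
#' @param dimensions embedding dimension (default 2).
#' @param n_starts number of starts (>= 1).
#' @param seed integer seed for the random starts.
#' @return Object of class `nmds_ordination`: list with `points` (centred
#'   coordinate matrix), `stress` (Kruskal stress-1, proportion), `best_start`,
#'   `n_starts`, `seed`.
#' @export
nmds_ordination <- function(d, dimensions = 2, n_starts = 20, seed = 1) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < 3L) stop("need at least three points")
  if (all(d == 0)) stop("degenerate distance matrix: all distances zero")
  starts <- vector("list", n_starts)
  starts[[1]] <- stats::cmdscale(d, k = dimensions)
  if (n_starts > 1L) {
    set.seed(seed)
    for (i in 2:n_starts)
      starts[[i]] <- matrix(stats::rnorm(n * dimensions), n, dimensions)
  }
  best <- NULL; best_i <- NA_integer_
  for (i in seq_len(n_starts)) {
    fit <- vegan::monoMDS(d, y = starts[[i]], k = dimensions,
                          model = "global")
    if (is.null(best) || fit$stress < best$stress) { best <- fit; best_i <- i }
  }
  pts <- scale(best$points, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("NMDS", seq_len(dimensions))
  structure(
    list(points = pts, stress = best$stress, best_start = best_i,
         n_starts = n_starts, seed = seed),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination of %d points in %d dimensions; stress = %.4g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' @param x an `nmds_ordination`.
#' @param groups optional factor of group labels for colouring and 95%
#'   normal-theory confidence ellipses per group.
#' @param ellipses draw per-group ellipses (needs >= 3 points per group).
#' @param ... passed to [graphics::plot()].
#' @rdname nmds_ordination
#' @export
plot.nmds_ordination <- function(x, groups = NULL, ellipses = TRUE, ...) {
  pts <- x$points
  col <- "black"
  if (!is.null(groups)) {
    groups <- factor(groups)
    pal <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
    col <- pal[as.integer(groups)]
  }
  graphics::plot(pts[, 1], pts[, 2], col = col, pch = 19,
                 xlab = colnames(pts)[1], ylab = colnames(pts)[2],
                 main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  if (!is.null(groups) && ellipses) {
    for (lv in levels(groups)) {
      sub <- pts[groups == lv, , drop = FALSE]
      if (nrow(sub) < 3L) next
      ctr <- colMeans(sub); cv <- stats::cov(sub)
      theta <- seq(0, 2 * pi, length.out = 100)
      circ <- cbind(cos(theta), sin(theta))
      rad <- sqrt(stats::qchisq(0.95, 2))
      ell <- sweep(circ %*% chol(cv) * rad, 2, ctr, "+")
      graphics::lines(ell, col = pal[match(lv, levels(groups))])
    }
    graphics::legend("topright", legend = levels(groups), col = pal,
                     pch = 19, bty = "n")
  }
  invisible(x)
}

permanova_F <- function(D2, groups) {
  N <- nrow(D2)
  lv <- levels(groups)
  k <- length(lv)
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  for (g in lv) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (N - k))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: with N observations in k groups,
#' total sum of squares \eqn{SS_T = \sum_{i<j} d_{ij}^2 / N}, within-group
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g}, and pseudo-F
#' \eqn{F = (SS_B/(k-1)) / (SS_W/(N-k))} with \eqn{SS_B = SS_T - SS_W}. The
#' p-value is the add-one permutation estimate
#' \eqn{(1 + \#\{F^\pi \ge F\}) / (B + 1)} under random relabelling. On
#' univariate data with Euclidean distance the pseudo-F equals the classical
#' one-way ANOVA F.
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @param groups factor (or coercible) of group labels, every group
#'   non-empty, at least two groups.
#' @param n_permutations number of permutations (>= 99; default 9999).
#' @param seed integer seed; mandatory so reports are reproducible.
#' @return Object of class `permanova`: list with `df` (between, within),
#'   `ss` (between, within, total), `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 9999, seed) {
  if (missing(seed)) stop("a seed is required for the permutation test")
  D <- as.matrix(d)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  groups <- droplevels(factor(groups))
  if (length(groups) != nrow(D))
    stop("groups length does not match the distance matrix")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) == 0L)) stop("empty group")
  if (n_permutations < 99) stop("use at least 99 permutations")
  D2 <- D^2
  N <- nrow(D2); k <- nlevels(groups)
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (k - 1)) / (ss_within / (N - k))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    f_perm <- permanova_F(D2, groups[sample.int(N)])
    if (f_perm >= f_obs) exceed <- exceed + 1L
  }
  structure(
    list(df = c(between = k - 1L, within = N - k),
         ss = c(between = ss_between, within = ss_within,
                total = ss_total),
         pseudo_F = f_obs,
         p_value = (1 + exceed) / (n_permutations + 1),
         n_permutations = n_permutations, seed = seed),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_permutations, "permutations, seed", x$seed, ")\n")
  cat(sprintf("  Df = %d, %d; pseudo-F = %.4g; P = %.4g\n",
              x$df["between"], x$df["within"], x$pseudo_F, x$p_value))
  cat(sprintf("  SS between = %.4g, within = %.4g, total = %.4g\n",
              x$ss["between"], x$ss["within"], x$ss["total"]))
  invisible(x)
}
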