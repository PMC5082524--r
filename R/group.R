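# Group-level inference: one-sample Z maps, sign-flip permutation
# cluster-extent FWE control, and cohort summary statistics.

# Coerce a list of 3-D arrays (or a matrix) to voxels x subjects.
maps_to_matrix <- function(maps) {
  if (is.matrix(maps)) return(list(Y = maps, dim = attr(maps, "grid_shape")))
  stopifnot(is.list(maps), length(maps) >= 1)
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), logical(1)))) {
    stop("maps are not on a common grid", call. = FALSE)
  }
  list(Y = vapply(maps, as.numeric, numeric(prod(d))), dim = d)
}

# One-sample t across columns of voxels x subjects matrix.
one_sample_t <- function(Y) {
  n <- ncol(Y)
  m <- rowMeans(Y)
  v <- (rowSums(Y^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  list(t = ifelse(se > 0, m / se, 0), mean = m, se = se, dof = n - 1)
}

#' Group one-sample Z map across subjects' contrast maps
#'
#' Per-voxel one-sample t of the subject contrast values against zero,
#' converted to Z by the matched log-tail quantile mapping. Voxels with
#' zero between-subject variance are set to `sign(mean) * z_cap` (0 when
#' all values are 0) rather than infinity.
#'
#' @param contrast_maps List of >= 3 template-space 3-D arrays (one per
#'   subject), or a voxels x subjects matrix.
#' @param z_cap Cap for zero-variance voxels (default 8.2).
#' @param space Optional `template_space` carried into the result.
#' @return A `group_zmap`: `data` (array or vector of Z), `n_subjects`,
#'   `dof`, `space`.
#' @export
group_one_sample_z <- function(contrast_maps, z_cap = 8.2, space = NULL) {
  mm <- maps_to_matrix(contrast_maps)
  n <- ncol(mm$Y)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  st <- one_sample_t(mm$Y)
  z <- t_to_z(st$t, st$dof)
  zero_var <- st$se == 0 & st$mean != 0
  z[zero_var] <- sign(st$mean[zero_var]) * z_cap
  data <- if (!is.null(mm$dim)) array(z, dim = mm$dim) else z
  structure(list(data = data, n_subjects = n, dof = n - 1, space = space),
            class = "group_zmap")
}

#' Cluster-extent FWE correction by sign-flip permutation
#'
#' Clusters of the group one-sample map above the cluster-forming threshold
#' `z_form` are tested against the permutation null distribution of the
#' maximum suprathreshold cluster size obtained by randomly flipping each
#' subject's map sign (valid under symmetric errors). A cluster is retained
#' iff its permutation p-value `(1 + #{null >= size}) / (n_perm + 1)` is
#' <= `alpha`. Thresholding is done on the equivalent t scale (the t -> Z
#' map is monotone), so observed and permuted statistics are treated
#' identically.
#'
#' @param contrast_maps List of per-subject template-space 3-D arrays, or a
#'   voxels x subjects matrix with a `grid_shape` attribute.
#' @param z_form Cluster-forming threshold on the Z scale (default 2.3).
#' @param alpha FWE level (default 0.05).
#' @param n_perm Number of sign-flip permutations (>= 100; default 199, for
#'   which the permutation p-value grid contains `alpha = 0.05` exactly:
#'   10/200).
#' @param seed RNG seed for the flips.
#' @param connectivity Cluster connectivity (default 26).
#' @return List with `clusters` (the observed `cluster_set`), `p_values`
#'   per cluster, `significant` (logical per cluster), `mask` (logical
#'   array of voxels in significant clusters), `null_max_sizes`,
#'   `t_form`, `dof`.
#' @export
cluster_extent_correct <- function(contrast_maps, z_form = 2.3, alpha = 0.05,
                                   n_perm = 199, seed = 1,
                                   connectivity = 26L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  mm <- maps_to_matrix(contrast_maps)
  if (is.null(mm$dim)) stop("grid shape unknown; supply 3-D arrays",
                            call. = FALSE)
  Y <- mm$Y
  n <- ncol(Y)
  dof <- n - 1
  # t value whose tail probability matches the normal tail at z_form
  t_form <- stats::qt(stats::pnorm(z_form, lower.tail = FALSE, log.p = TRUE),
                      df = dof, lower.tail = FALSE, log.p = TRUE)
  SS <- rowSums(Y^2)

  max_cluster_size <- function(t) {
    idx <- which(t > t_form)   # NA-safe: NAs are not TRUE
    if (!length(idx)) return(0L)
    max(tabulate(label_components_idx(idx, mm$dim, connectivity)))
  }

  st <- one_sample_t(Y)
  obs_bin <- array(st$t > t_form, dim = mm$dim)
  clusters <- find_clusters(obs_bin, connectivity = connectivity,
                            values = array(st$t, dim = mm$dim))

  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    M <- (Y %*% S) / n
    # SS recycles down columns; sign flips leave sums of squares unchanged
    V <- (SS - n * M * M) / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    vapply(seq_len(n_perm), function(p) max_cluster_size(Tm[, p]), integer(1))
  })

  p_values <- vapply(clusters$sizes, function(s) {
    (1 + sum(null_max >= s)) / (n_perm + 1)
  }, numeric(1))
  significant <- p_values <= alpha
  mask <- array(FALSE, dim = mm$dim)
  if (any(significant)) {
    keep <- which(significant)
    mask[clusters$labels %in% keep] <- TRUE
  }
  list(clusters = clusters, p_values = p_values, significant = significant,
       mask = mask, null_max_sizes = null_max, t_form = t_form, dof = dof,
       z_form = z_form, alpha = alpha, n_perm = n_perm, seed = seed)
}

#' Proportion of subjects with in-ROI activation per analysis cell
#'
#' Summarises per-subject activation flags into the proportion of subjects
#' with at least one suprathreshold in-ROI voxel for every requested
#' roi x z_threshold x fwhm cell.
#'
#' @param records data.frame with columns `subject`, `roi`, `z_threshold`,
#'   `fwhm`, `active` (logical).
#' @param rois,thresholds,fwhms Requested cell labels; default the levels
#'   present in `records`.
#' @return A `frequency_table` data.frame: roi, z_threshold, fwhm,
#'   n_with_cluster, n_subjects, proportion.
#' @export
frequency_table <- function(records, rois = unique(records$roi),
                            thresholds = unique(records$z_threshold),
                            fwhms = unique(records$fwhm)) {
  needed <- expand.grid(roi = rois, z_threshold = thresholds, fwhm = fwhms,
                        stringsAsFactors = FALSE)
  out <- needed
  out$n_with_cluster <- NA_integer_
  out$n_subjects <- NA_integer_
  missing_cells <- character(0)
  for (r in seq_len(nrow(needed))) {
    sel <- records$roi == needed$roi[r] &
      records$z_threshold == needed$z_threshold[r] &
      records$fwhm == needed$fwhm[r]
    if (!any(sel)) {
      missing_cells <- c(missing_cells,
                         sprintf("%s/z=%g/fwhm=%g", needed$roi[r],
                                 needed$z_threshold[r], needed$fwhm[r]))
      next
    }
    out$n_with_cluster[r] <- sum(records$active[sel])
    out$n_subjects[r] <- sum(sel)
  }
  if (length(missing_cells)) {
    stop("missing cells: ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  }
  out$proportion <- out$n_with_cluster / out$n_subjects
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Scene-versus-object preference indicator per subject and ROI
#'
#' Scores 1 iff the scene percent signal change exceeds the object percent
#' signal change (exact ties score 0).
#'
#' @param psc data.frame with columns `subject`, `roi`, `condition`
#'   (`"scenes"`/`"objects"`), `psc`.
#' @return Integer matrix (subjects x ROIs) of 0/1 scores.
#' @export
binomial_preference <- function(psc) {
  subjects <- unique(psc$subject)
  rois <- unique(psc$roi)
  out <- matrix(NA_integer_, length(subjects), length(rois),
                dimnames = list(as.character(subjects), rois))
  for (i in seq_along(subjects)) {
    for (j in seq_along(rois)) {
      s <- psc[psc$subject == subjects[i] & psc$roi == rois[j], , drop = FALSE]
      sc <- s$psc[s$condition == "scenes"]
      ob <- s$psc[s$condition == "objects"]
      if (length(sc) != 1 || length(ob) != 1) {
        stop(sprintf("missing condition for subject %s, roi %s",
                     subjects[i], rois[j]), call. = FALSE)
      }
      out[i, j] <- as.integer(sc > ob)
    }
  }
  out
}

#' Cochran's Q test for repeated binary measures
#'
#' Q = k(k-1) * sum_j (G_j - T/k)^2 / (k * sum_i L_i - sum_i L_i^2) with k
#' regions (columns), column totals G_j, row totals L_i and grand total T;
#' df = k - 1 and the p-value is the chi-square upper tail. (Reports of
#' this statistic sometimes print df = k; the correct reference
#' distribution has k - 1 degrees of freedom.) When every row is constant
#' the denominator is 0 and Q is defined as 0 with p = 1.
#'
#' @param binary Subject x region matrix with entries in {0, 1}
#'   (>= 2 subjects, >= 2 regions).
#' @return A `cochran_result`: `Q`, `df`, `p_value`, `column_totals`.
#' @export
cochrans_q <- function(binary) {
  binary <- as.matrix(binary)
  if (nrow(binary) < 2 || ncol(binary) < 2) {
    stop("need >= 2 subjects and >= 2 regions", call. = FALSE)
  }
  if (!all(binary %in% c(0, 1))) {
    stop("entries must be 0 or 1", call. = FALSE)
  }
  k <- ncol(binary)
  G <- colSums(binary)
  L <- rowSums(binary)
  T_ <- sum(binary)
  denom <- k * sum(L) - sum(L^2)
  Q <- if (denom == 0) 0 else k * (k - 1) * sum((G - T_ / k)^2) / denom
  df <- k - 1
  p <- if (denom == 0) 1 else stats::pchisq(Q, df = df, lower.tail = FALSE)
  structure(list(Q = Q, df = df, p_value = p, column_totals = G),
            class = "cochran_result")
}

#' @export
print.cochran_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.4g\n", x$Q, x$df, x$p_value))
  invisible(x)
}

#' Paired t statistic and Cohen's d for paired samples
#'
#' t = mean(d) / (SD(d) / sqrt(n)) and Cohen's d = mean(d) / SD(d) for the
#' paired differences d = a - b.
#'
#' @param psc_a,psc_b Equal-length paired numeric samples (n >= 2).
#' @return List with `t`, `cohen_d`, `dof`, `p_value` (two-sided).
#' @export
paired_effect <- function(psc_a, psc_b) {
  stopifnot(length(psc_a) == length(psc_b), length(psc_a) >= 2)
  d <- psc_a - psc_b
  s <- stats::sd(d)
  n <- length(d)
  if (s == 0) {
    if (all(d == 0)) {
      # identical samples: no effect, not an error
      return(list(t = 0, cohen_d = 0, dof = n - 1, p_value = 1))
    }
    stop("zero SD of paired differences", call. = FALSE)
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, cohen_d = mean(d) / s, dof = n - 1,
       p_value = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE))
}
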