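#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' Two-sided Mann-Whitney comparison of a structural parameter between two
#' diagnosis groups. For a combined sample size of at most 20 the null
#' distribution of U is enumerated exactly over all rank assignments
#' (midranks for ties; two-sided p = Pr(|U - mu| >= |u_obs - mu|), which by
#' symmetry reduces to the usual two-tailed sum). Larger samples use the
#' normal approximation with tie-corrected variance. The method used is
#' recorded in the result.
#'
#' @param group_a_values,group_b_values numeric vectors, each non-empty.
#' @param exact_max_n maximum combined size for exact enumeration.
#' @return A list with `U` (statistic of group A), `p` (two-sided),
#'   `method` ("exact" or "normal_approx") and `stars` (the significance
#'   annotation convention: * p < 0.05, ** < 0.01, *** < 0.001,
#'   **** < 0.0001).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, complete separation
#' @export
mann_whitney <- function(group_a_values, group_b_values, exact_max_n = 20L) {
  a <- as.numeric(group_a_values)
  b <- as.numeric(group_b_values)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  ranks <- rank(c(a, b))  # midranks
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_max_n) {
    sets <- utils::combn(n, na)
    w <- colSums(matrix(ranks[sets], nrow = na))
    u_all <- w - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(ranks)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = u_obs, p = p, method = method, stars = p_stars(p))
}

#' Significance stars
#'
#' The annotation convention used throughout the reports: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001, `ns` otherwise.
#' p-values are always reported numerically alongside.
#'
#' @param p p-value.
#' @return Character annotation.
#' @export
p_stars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Correlation between structural parameters
#'
#' Pearson or Spearman correlation with a two-sided p-value. The method is
#' an explicit argument (the choice between the two depends on the
#' normality of the data and is left to the analyst); it is recorded in
#' the result.
#'
#' @param x_values,y_values numeric vectors of equal length >= 3.
#' @param method "pearson" or "spearman".
#' @return A list with `estimate` (r or rho), `p`, `method` and `stars`.
#' @export
correlate <- function(x_values, y_values, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x_values); y <- as.numeric(y_values)
  if (length(x) != length(y)) stop("`x_values` and `y_values` differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation coefficient undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method,
       stars = p_stars(ct$p.value))
}

#' Assemble a per-cusp report
#'
#' Aggregates every metric the pipeline computes for one cusp into a
#' machine-readable record: entire-cusp volume, calcification volume and
#' fraction, density-class volumes with the PVE-correction volume loss,
#' particle summary and thickness summary, together with the full
#' configuration snapshot and software version for provenance.
#'
#' @param sample_id cusp identifier (e.g. "N1.1"); the valve id is taken
#'   as the part before the last ".".
#' @param group_tag opaque diagnosis group label.
#' @param cusp_mask,calc_mask logical masks.
#' @param density a `density_masks` from [pve_decompose()].
#' @param particles a `particle_table` from [particle_metrics()].
#' @param thickness a summary from [thickness_summary()].
#' @param config the [pipeline_config()] used.
#' @return A list of class `cusp_report`.
#' @export
cusp_report <- function(sample_id, group_tag, cusp_mask, calc_mask, density,
                        particles, thickness, config) {
  cusp_vol <- mask_volume_mm3(cusp_mask, config$voxel_size_um)
  calc_vol <- mask_volume_mm3(calc_mask, config$voxel_size_um)
  structure(list(
    sample_id = sample_id,
    valve_id = sub("\\.[^.]*$", "", sample_id),
    group_tag = group_tag,
    cusp_volume_mm3 = cusp_vol,
    calc_volume_mm3 = calc_vol,
    calc_volume_fraction = calc_vol / cusp_vol,
    density_volumes_mm3 = as.list(density$volumes_mm3),
    volume_loss_fraction = density$volume_loss_fraction,
    particles = particles$summary,
    thickness = thickness[c("mean_thickness_mm", "fraction_below_threshold",
                            "thin_threshold_mm")],
    thickness_histogram = thickness$histogram,
    provenance = list(package_version = as.character(utils::packageVersion("valve3d")),
                      config = unclass(config))
  ), class = "cusp_report")
}

#' Aggregate cusp reports to the valve level
#'
#' The valve calcification fraction pools numerators and denominators over
#' the valve's cusps (sum of calcification volumes over sum of cusp
#' volumes); it therefore always lies between the per-cusp fractions.
#'
#' @param cusp_reports list of 1-3 `cusp_report`s sharing one valve id.
#' @return A list with `valve_id`, `n_cusps`, `cusp_volume_mm3`,
#'   `calc_volume_mm3` and `calc_volume_fraction`.
#' @export
aggregate_valve <- function(cusp_reports) {
  if (length(cusp_reports) == 0L) stop("no cusp reports", call. = FALSE)
  ids <- vapply(cusp_reports, function(r) r$valve_id, character(1))
  if (length(unique(ids)) != 1L) {
    stop("cusp reports belong to different valves: ", paste(unique(ids), collapse = ", "),
         call. = FALSE)
  }
  cusp_vol <- sum(vapply(cusp_reports, function(r) r$cusp_volume_mm3, numeric(1)))
  calc_vol <- sum(vapply(cusp_reports, function(r) r$calc_volume_mm3, numeric(1)))
  list(valve_id = ids[1], n_cusps = length(cusp_reports),
       cusp_volume_mm3 = cusp_vol, calc_volume_mm3 = calc_vol,
       calc_volume_fraction = calc_vol / cusp_vol)
}

#' Write a cusp report as JSON
#'
#' @param report a `cusp_report`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_cusp_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
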