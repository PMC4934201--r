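#' Retrieval window definition
#'
#' The wavelength anchors and (for SFM) polynomial degrees of one retrieval
#' configuration. FLD uses a single left shoulder; 3FLD uses one shoulder on
#' each side of the band; SFM uses all samples between the outermost left and
#' right anchors, fitting reflectance and fluorescence polynomials of degrees
#' `degree_r` and `degree_f`.
#'
#' @param algorithm One of `"FLD"`, `"3FLD"`, `"SFM"`.
#' @param band `"O2A"` or `"O2B"`.
#' @param lambda_in In-band (absorption bottom) wavelength, nm.
#' @param lambda_left Left anchor wavelength(s), nm (all < `lambda_in`).
#' @param lambda_right Right anchor wavelength(s), nm (all > `lambda_in`;
#'   empty for FLD).
#' @param degree_r,degree_f Polynomial degrees for SFM reflectance and
#'   fluorescence (with `degree_r >= degree_f`).
#' @return A list of class `retrieval_window`.
#' @export
retrieval_window <- function(algorithm = c("FLD", "3FLD", "SFM"),
                             band = c("O2A", "O2B"),
                             lambda_in, lambda_left,
                             lambda_right = numeric(),
                             degree_r = NA_integer_, degree_f = NA_integer_) {
  algorithm <- match.arg(algorithm)
  band <- match.arg(band)
  if (any(lambda_left >= lambda_in)) {
    rlang::abort("All `lambda_left` must be < `lambda_in`.")
  }
  if (length(lambda_right) && any(lambda_right <= lambda_in)) {
    rlang::abort("All `lambda_right` must be > `lambda_in`.")
  }
  if (algorithm == "3FLD" && !length(lambda_right)) {
    rlang::abort("3FLD needs a right shoulder.")
  }
  if (algorithm == "SFM") {
    if (is.na(degree_r) || is.na(degree_f)) {
      rlang::abort("SFM needs `degree_r` and `degree_f`.")
    }
    if (degree_r < degree_f) rlang::abort("SFM expects `degree_r` >= `degree_f`.")
    if (!length(lambda_right)) rlang::abort("SFM needs a right window bound.")
  }
  structure(list(algorithm = algorithm, band = band, lambda_in = lambda_in,
                 lambda_left = lambda_left, lambda_right = lambda_right,
                 degree_r = degree_r, degree_f = degree_f),
            class = "retrieval_window")
}

result_row <- function(window, lambda_used, f_value) {
  tibble::tibble(algorithm = window$algorithm, band = window$band,
                 lambda_in = lambda_used, f_value = f_value)
}

#' Fraunhofer line depth (FLD) retrieval
#'
#' Two-channel retrieval: with the in-band channel at `lambda_in` and the
#' shoulder channel at the (first) left anchor,
#' `F = (E_out * L_in - E_in * L_out) / (E_out - E_in)`. Exact when the true
#' reflectance and fluorescence are both constant across the two channels.
#' `E` may be irradiance or panel-equivalent radiance; the formula is
#' invariant to the pi factor between them.
#'
#' @param E Downwelling spectrum.
#' @param L Upwelling radiance spectrum on the same grid.
#' @param window A [retrieval_window()].
#' @return One-row tibble: `algorithm`, `band`, `lambda_in` (snapped to the
#'   grid), `f_value` (radiance at `lambda_in`).
#' @export
fld <- function(E, L, window) {
  grid <- stopifnot_same_grid(E, L)
  i_in <- snap_index(grid, window$lambda_in)
  i_out <- snap_index(grid, window$lambda_left[1])
  f <- fld_values(E$value[i_in], E$value[i_out], L$value[i_in], L$value[i_out])
  result_row(window, grid[i_in], f)
}

fld_values <- function(e_in, e_out, l_in, l_out) {
  if (any(abs(e_out - e_in) < 1e-12)) {
    rlang::abort("Degenerate band: no absorption contrast between channels.")
  }
  unname((e_out * l_in - e_in * l_out) / (e_out - e_in))
}

#' Three-channel FLD (3FLD) retrieval
#'
#' Interpolates the left and right shoulders to the in-band wavelength with
#' weights `w_left = (lambda_right - lambda_in) / (lambda_right - lambda_left)`
#' and `w_right = 1 - w_left` (applied to both `E` and `L`), then applies the
#' FLD formula. Exact when the true reflectance varies linearly across the
#' band and the fluorescence is constant.
#'
#' @inheritParams fld
#' @export
three_fld <- function(E, L, window) {
  grid <- stopifnot_same_grid(E, L)
  i_in <- snap_index(grid, window$lambda_in)
  i_l <- snap_index(grid, window$lambda_left[1])
  i_r <- snap_index(grid, window$lambda_right[1])
  w <- three_fld_weights(grid[i_l], grid[i_in], grid[i_r])
  e_out <- w[1] * E$value[i_l] + w[2] * E$value[i_r]
  l_out <- w[1] * L$value[i_l] + w[2] * L$value[i_r]
  f <- fld_values(E$value[i_in], e_out, L$value[i_in], l_out)
  result_row(window, grid[i_in], f)
}

three_fld_weights <- function(lambda_l, lambda_in, lambda_r) {
  d <- lambda_r - lambda_l
  c(w_left = (lambda_r - lambda_in) / d, w_right = (lambda_in - lambda_l) / d)
}

#' Spectral fitting method (SFM) retrieval
#'
#' Fits the forward model `L(lambda) = E(lambda) * r(lambda) / pi + F(lambda)`
#' by linear least squares over every grid sample between the outermost left
#' and right anchors, with `r` and `F` polynomials of degrees `degree_r` and
#' `degree_f` in `(lambda - lambda_in)`. Centring the wavelengths on
#' `lambda_in` conditions the design matrix, and the retrieved fluorescence is
#' the fitted `F` constant term (its value at `lambda_in`).
#'
#' @inheritParams fld
#' @export
sfm <- function(E, L, window) {
  grid <- stopifnot_same_grid(E, L)
  i_in <- snap_index(grid, window$lambda_in)
  sel <- sfm_sample_index(grid, window)
  f <- sfm_fit(E$value[sel], L$value[sel], grid[sel] - window$lambda_in,
               window$degree_r, window$degree_f)
  result_row(window, grid[i_in], f)
}

sfm_sample_index <- function(grid, window) {
  lo <- min(window$lambda_left)
  hi <- max(window$lambda_right)
  sel <- which(grid >= lo - 1e-9 & grid <= hi + 1e-9)
  if (length(sel) < window$degree_r + window$degree_f + 2) {
    rlang::abort("Underdetermined SFM system: window holds fewer samples than coefficients.")
  }
  sel
}

sfm_design <- function(e, x, degree_r, degree_f) {
  xr <- outer(x, 0:degree_r, `^`)
  xf <- outer(x, 0:degree_f, `^`)
  cbind(e * xr / pi, xf)
}

sfm_fit <- function(e, l, x, degree_r, degree_f) {
  X <- sfm_design(e, x, degree_r, degree_f)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    rlang::warn("Collinear SFM design matrix; fit is not unique.")
  }
  beta <- qr.coef(qr_x, l)
  beta[is.na(beta)] <- 0
  unname(beta[degree_r + 2]) # F polynomial constant term = F(lambda_in)
}

#' Retrieve SIF with the algorithm named in the window
#'
#' @inheritParams fld
#' @export
retrieve_sif <- function(E, L, window) {
  switch(window$algorithm,
         "FLD" = fld(E, L, window),
         "3FLD" = three_fld(E, L, window),
         "SFM" = sfm(E, L, window))
}

# Vectorised retrieval over paired ensembles stored as matrices
# (rows = wavelengths, columns = realizations).
retrieve_many <- function(E_mat, L_mat, grid, window) {
  if (window$algorithm == "FLD") {
    i_in <- snap_index(grid, window$lambda_in)
    i_out <- snap_index(grid, window$lambda_left[1])
    return(fld_values(E_mat[i_in, ], E_mat[i_out, ], L_mat[i_in, ], L_mat[i_out, ]))
  }
  if (window$algorithm == "3FLD") {
    i_in <- snap_index(grid, window$lambda_in)
    i_l <- snap_index(grid, window$lambda_left[1])
    i_r <- snap_index(grid, window$lambda_right[1])
    w <- three_fld_weights(grid[i_l], grid[i_in], grid[i_r])
    e_out <- w[1] * E_mat[i_l, ] + w[2] * E_mat[i_r, ]
    l_out <- w[1] * L_mat[i_l, ] + w[2] * L_mat[i_r, ]
    return(fld_values(E_mat[i_in, ], e_out, L_mat[i_in, ], l_out))
  }
  sel <- sfm_sample_index(grid, window)
  x <- grid[sel] - window$lambda_in
  vapply(seq_len(ncol(E_mat)), function(j) {
    sfm_fit(E_mat[sel, j], L_mat[sel, j], x, window$degree_r, window$degree_f)
  }, numeric(1))
}

#' Monte-Carlo retrieval statistics over a noise ensemble
#'
#' Pairs realization `i` of the downwelling ensemble with realization `i` of
#' the upwelling ensemble, retrieves SIF from each pair, and summarises the
#' draw as mean, standard deviation and bias against the injected truth.
#' Negative retrievals under noise are kept as-is.
#'
#' @param E_ens,L_ens Wide ensemble tibbles from [noisy_ensemble()] (first
#'   column `wavelength_nm`, one column per realization), of equal size.
#' @param window A [retrieval_window()].
#' @param truth Injected fluorescence radiance at `lambda_in`.
#' @return A list of class `sif_ensemble_stats` with elements `stats` (one-row
#'   tibble: algorithm, band, lambda_in, mean, sd, bias, truth, n) and
#'   `f_values` (per-realization retrievals).
#' @export
retrieve_ensemble <- function(E_ens, L_ens, window, truth) {
  if (ncol(E_ens) != ncol(L_ens) || ncol(E_ens) < 2) {
    rlang::abort("Ensembles must have equal, positive numbers of realizations.")
  }
  if (any(abs(E_ens$wavelength_nm - L_ens$wavelength_nm) > 1e-9)) {
    rlang::abort("Ensembles must share an identical wavelength grid.")
  }
  grid <- E_ens$wavelength_nm
  f <- retrieve_many(ensemble_matrix(E_ens), ensemble_matrix(L_ens), grid, window)
  n <- length(f)
  structure(list(
    stats = tibble::tibble(
      algorithm = window$algorithm, band = window$band,
      lambda_in = window$lambda_in,
      mean = mean(f), sd = if (n > 1) stats::sd(f) else 0,
      bias = mean(f) - truth, truth = truth, n = n
    ),
    f_values = f
  ), class = "sif_ensemble_stats")
}

#' @export
print.sif_ensemble_stats <- function(x, ...) {
  cat("<sif_ensemble_stats>\n")
  print(x$stats)
  invisible(x)
}

#' Tidy per-realization retrievals
#' @param x A `sif_ensemble_stats`.
#' @param ... Unused.
#' @return Tibble with one row per realization.
#' @importFrom generics tidy
#' @export
#' @method tidy sif_ensemble_stats
tidy.sif_ensemble_stats <- function(x, ...) {
  tibble::tibble(realization = seq_along(x$f_values),
                 algorithm = x$stats$algorithm, band = x$stats$band,
                 f_value = x$f_values)
}

#' One-row ensemble summary
#' @inheritParams tidy.sif_ensemble_stats
#' @importFrom generics glance
#' @export
#' @method glance sif_ensemble_stats
glance.sif_ensemble_stats <- function(x, ...) {
  x$stats
}
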