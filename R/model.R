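#' Parameters of the district lichen biomass model
#'
#' The discrete annual model `b_t = b_{t-1} + g_{t-1} - e_{t-1} - w_{t-1}`
#' tracks district-mean forage-lichen dry biomass (g m^-2, equal to tonnes
#' km^-2). Relative growth follows the experimentally derived power law
#' `R = a b^-k` (defaults a = 1.95, k = 0.1), so absolute plot-scale growth
#' is `b R - b`, scaled at the district level by a Jensen-type landscape
#' factor f. Intake is `e = i d` with `i` the dry lichen metabolised per
#' reindeer-year (tonnes; 0.676 for a pure winter district, half that for
#' mixed year-round use) and `d` the density in reindeer-years km^-2. The
#' non-ingestive loss (trampling, wastage) is `w = b d l`, a fraction `l`
#' of standing biomass per reindeer-year km^-2.
#'
#' @param growth_coeff a in R = a b^-k.
#' @param growth_exp k in R = a b^-k (0 < k < 1).
#' @param intake_t_per_reindeer_year i, tonnes dry lichen metabolised per
#'   reindeer-year.
#' @param loss_factor l, proportion of standing biomass upended annually
#'   per reindeer-year km^-2.
#' @param energy_req_mj_day wintertime metabolisable energy requirement of
#'   a mid-sized reindeer (MJ day^-1).
#' @param energy_content_mj_kg metabolisable energy of dry reindeer lichen
#'   (MJ kg^-1).
#' @return A `model_params` list.
#' @export
model_params <- function(growth_coeff = 1.95, growth_exp = 0.1,
                         intake_t_per_reindeer_year = 0.676,
                         loss_factor = 0.019,
                         energy_req_mj_day = 20,
                         energy_content_mj_kg = 10.8) {
  if (growth_coeff <= 0) rlang::abort("growth_coeff must be positive")
  if (growth_exp <= 0 || growth_exp >= 1) {
    rlang::abort("growth_exp must be in (0, 1)")
  }
  if (intake_t_per_reindeer_year < 0 || loss_factor < 0) {
    rlang::abort("intake and loss must be non-negative")
  }
  structure(list(
    growth_coeff = growth_coeff, growth_exp = growth_exp,
    intake_t_per_reindeer_year = intake_t_per_reindeer_year,
    loss_factor = loss_factor,
    energy_req_mj_day = energy_req_mj_day,
    energy_content_mj_kg = energy_content_mj_kg
  ), class = "model_params")
}

#' Annual relative lichen growth R = a b^-k
#'
#' @param b standing biomass (g m^-2); R diverges as b -> 0, but the
#'   associated absolute growth `b (R - 1)` tends to 0 there.
#' @param params a [model_params()].
#' @return Dimensionless relative growth (Inf at b = 0).
#' @export
relative_growth <- function(b, params = model_params()) {
  if (any(b < 0, na.rm = TRUE)) rlang::abort("biomass must be non-negative")
  params$growth_coeff * b^(-params$growth_exp)
}

#' Absolute annual plot-scale growth b R(b) - b
#'
#' `a b^(1-k) - b`: zero at b = 0 and at the equilibrium a^(1/k), with a
#' single interior maximum at b = (a (1 - k))^(1/k).
#'
#' @inheritParams relative_growth
#' @return Growth in g m^-2 yr^-1 (0 at b = 0).
#' @export
plot_growth <- function(b, params = model_params()) {
  if (any(b < 0, na.rm = TRUE)) rlang::abort("biomass must be non-negative")
  ifelse(b > 0,
         params$growth_coeff * b^(1 - params$growth_exp) - b,
         0)
}

#' Analytic anchors of the growth law
#'
#' @param params a [model_params()].
#' @return A tibble with the biomass of maximum growth, the maximum growth
#'   itself, and the zero-growth equilibrium biomass (all g m^-2).
#' @export
growth_law_anchors <- function(params = model_params()) {
  a <- params$growth_coeff; k <- params$growth_exp
  b_max <- (a * (1 - k))^(1 / k)
  tibble::tibble(
    b_at_max_growth = b_max,
    max_growth = plot_growth(b_max, params),
    b_zero_growth = a^(1 / k)
  )
}

#' Jensen-type landscape growth factor
#'
#' Ratio of the mean pointwise growth over a sample of biomass values
#' (a dense random point cloud on a biomass map) to the growth evaluated
#' at the sample mean. Because growth is concave on the relevant range,
#' f <= 1, with equality only for a homogeneous landscape; heterogeneity
#' lowers realised district growth.
#'
#' @param point_biomasses sample of biomass values b_r (g m^-2).
#' @param params a [model_params()].
#' @return f in (0, 1] (can drop to 0 or below for extreme samples, which
#'   is flagged as an error when the denominator is non-positive).
#' @export
landscape_factor <- function(point_biomasses, params = model_params()) {
  b <- point_biomasses[!is.na(point_biomasses)]
  if (!length(b)) rlang::abort("empty biomass sample")
  m <- mean(b)
  eq <- params$growth_coeff^(1 / params$growth_exp)
  if (m <= 0 || m >= eq) {
    rlang::abort(sprintf(
      "landscape factor undefined: mean biomass %.3g outside (0, %.0f)", m, eq))
  }
  mean(plot_growth(b, params)) / plot_growth(m, params)
}

#' Interpolate landscape factors to all model years
#'
#' Mapped years anchor the series; intermediate years are linearly
#' interpolated and years beyond the first/last anchor take the nearest
#' anchor's value.
#'
#' @param anchors tibble `year`, `f` at the mapped years.
#' @param years all years needed by the simulation.
#' @return A tibble: `year`, `f`, `provenance` ("computed"/"interpolated").
#' @export
interpolate_factor <- function(anchors, years) {
  if (!nrow(anchors)) rlang::abort("need at least one anchor year")
  f <- if (nrow(anchors) == 1) {
    rep(anchors$f[1], length(years))
  } else {
    stats::approx(anchors$year, anchors$f, xout = years, rule = 2)$y
  }
  tibble::tibble(
    year = as.integer(years), f = f,
    provenance = ifelse(years %in% anchors$year, "computed", "interpolated")
  )
}

#' Reindeer-year density of a district
#'
#' Animal density scaled by the fraction of the year the animals are
#' present: 2.3 animals km^-2 spending 157 days in a winter district is
#' about one reindeer-year km^-2.
#'
#' @param count animals counted.
#' @param area_km2 district area.
#' @param occupancy_days days per year the population spends in the
#'   district (0-365).
#' @return Density in reindeer-years km^-2.
#' @export
reindeer_year_density <- function(count, area_km2, occupancy_days) {
  if (any(area_km2 <= 0)) rlang::abort("area must be positive")
  if (any(occupancy_days < 0 | occupancy_days > 365)) {
    rlang::abort("occupancy_days must be within [0, 365]")
  }
  (count / area_km2) * (occupancy_days / 365)
}

#' Dry lichen metabolised per reindeer-year
#'
#' Energy requirement divided by the energy content of dry lichen, over the
#' days of a reindeer-year: 20 MJ day^-1 / 10.8 MJ kg^-1 * 365 d = 676 kg.
#'
#' @param energy_req_mj_day metabolic requirement (MJ day^-1).
#' @param energy_content_mj_kg energy in dry lichen (MJ kg^-1).
#' @param days days counted (365 for a full reindeer-year).
#' @return Dry lichen mass in kg.
#' @export
metabolic_intake_constant <- function(energy_req_mj_day = 20,
                                      energy_content_mj_kg = 10.8,
                                      days = 365) {
  if (energy_content_mj_kg <= 0) rlang::abort("energy content must be positive")
  energy_req_mj_day / energy_content_mj_kg * days
}

MODEL_VARIANTS <- c("full", "no_loss", "intake_only", "no_intake")

#' One annual step of the district biomass model
#'
#' All three fluxes are computed from the start-of-year biomass: growth
#' `g = f (b R - b)`, intake `e = i d`, loss `w = b d l`. Variants zero
#' individual terms (no_loss: w = 0; intake_only: g = w = 0; no_intake:
#' e = 0). Biomass is floored at zero; when the floor binds, the step is
#' flagged.
#'
#' @param b start-of-year biomass (g m^-2).
#' @param d reindeer-year density (km^-2).
#' @param f landscape growth factor in (0, 1].
#' @param params a [model_params()].
#' @param variant one of "full", "no_loss", "intake_only", "no_intake".
#' @return A list: `g`, `e`, `w`, `b_next`, `clamped`.
#' @export
annual_step <- function(b, d, f, params = model_params(), variant = "full") {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (b < 0 || d < 0) rlang::abort("biomass and density must be non-negative")
  if (f <= 0 || f > 1) rlang::abort("landscape factor must be in (0, 1]")
  g <- f * plot_growth(b, params)
  e <- params$intake_t_per_reindeer_year * d
  w <- b * d * params$loss_factor
  if (variant == "no_loss") w <- 0
  if (variant == "intake_only") { g <- 0; w <- 0 }
  if (variant == "no_intake") e <- 0
  raw <- b + g - e - w
  list(g = g, e = e, w = w, b_next = max(0, raw), clamped = raw < 0)
}

#' Simulate the district biomass trajectory
#'
#' Iterates [annual_step()] over the given years under the supplied density
#' and landscape-factor series. Start-of-year biomass, the three annual
#' fluxes and clamp events are reported per year; outside clamped years
#' the bookkeeping identity `b_{t+1} = b_t + g_t - e_t - w_t` holds
#' exactly.
#'
#' @param b0 biomass at the start of the first year (g m^-2).
#' @param years integer vector of consecutive simulation years.
#' @param densities tibble `year`, `d` covering all years.
#' @param fts tibble `year`, `f` covering all years (or a single number
#'   used for every year).
#' @param params a [model_params()].
#' @param variant model variant (see [annual_step()]).
#' @return A `lichen_trajectory` tibble: `year`, `b`, `g`, `e`, `w`,
#'   `b_next`, `clamped`, `variant`.
#' @export
simulate_biomass <- function(b0, years, densities, fts = 1,
                             params = model_params(), variant = "full") {
  variant <- match.arg(variant, MODEL_VARIANTS)
  years <- as.integer(years)
  if (is.numeric(fts) && !is.data.frame(fts)) {
    fts <- tibble::tibble(year = years, f = fts)
  }
  miss_d <- setdiff(years, densities$year)
  if (length(miss_d)) {
    rlang::abort(sprintf("density series missing year(s): %s",
                         paste(miss_d, collapse = ", ")))
  }
  miss_f <- setdiff(years, fts$year)
  if (length(miss_f)) {
    rlang::abort(sprintf("landscape-factor series missing year(s): %s",
                         paste(miss_f, collapse = ", ")))
  }
  d <- densities$d[match(years, densities$year)]
  f <- fts$f[match(years, fts$year)]
  n <- length(years)
  b <- g <- e <- w <- bn <- numeric(n)
  cl <- logical(n)
  bt <- b0
  for (t in seq_len(n)) {
    st <- annual_step(bt, d[t], f[t], params, variant)
    b[t] <- bt; g[t] <- st$g; e[t] <- st$e; w[t] <- st$w
    bn[t] <- st$b_next; cl[t] <- st$clamped
    bt <- st$b_next
  }
  out <- tibble::tibble(year = years, b = b, g = g, e = e, w = w,
                        b_next = bn, clamped = cl, variant = variant)
  class(out) <- c("lichen_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "b0") <- b0
  out
}

#' Fit the loss parameter l to a reconstructed biomass history
#'
#' Minimises the sum of squared differences between the simulated
#' trajectory and the sparse reconstructed (observed) biomass series over
#' l >= 0, by bounded scalar minimisation (Brent via [stats::optimize()])
#' refined from a coarse grid over the search interval; the l = 0 boundary
#' is checked explicitly.
#'
#' @param observed tibble `year`, `biomass` (>= 2 years inside the
#'   simulated range).
#' @param b0 initial biomass (g m^-2).
#' @param densities tibble `year`, `d`.
#' @param fts tibble `year`, `f` (or a single number).
#' @param params a [model_params()]; its `loss_factor` is ignored.
#' @param l_range search interval for l (default [0, 0.5]).
#' @param variant model variant under which l is fitted.
#' @return A `loss_fit`: `l_hat`, `sse`, per-year residuals, the trajectory
#'   at the optimum, and the search settings.
#' @export
fit_loss_parameter <- function(observed, b0, densities, fts = 1,
                               params = model_params(),
                               l_range = c(0, 0.5), variant = "full") {
  years <- densities$year
  obs <- dplyr::filter(observed, .data$year %in% years)
  if (nrow(obs) < 2) {
    rlang::abort("need >= 2 observation years within the simulated range")
  }
  sse_of <- function(l) {
    p <- params; p$loss_factor <- l
    sim <- simulate_biomass(b0, years, densities, fts, p, variant)
    sum((sim$b[match(obs$year, sim$year)] - obs$biomass)^2)
  }
  grid_l <- seq(l_range[1], l_range[2], length.out = 51)
  grid_sse <- vapply(grid_l, sse_of, numeric(1))
  if (any(!is.finite(grid_sse))) rlang::abort("non-finite fitting objective")
  i <- which.min(grid_sse)
  lo <- grid_l[max(1, i - 1)]; hi <- grid_l[min(length(grid_l), i + 1)]
  opt <- stats::optimize(sse_of, c(lo, hi), tol = 1e-8)
  cands <- tibble::tibble(l = c(opt$minimum, l_range[1]),
                          sse = c(opt$objective, grid_sse[1]))
  best <- cands[which.min(cands$sse), ]
  p <- params; p$loss_factor <- best$l
  sim <- simulate_biomass(b0, years, densities, fts, p, variant)
  resid <- dplyr::mutate(obs,
    fitted = sim$b[match(obs$year, sim$year)],
    residual = .data$fitted - .data$biomass)
  structure(list(
    l_hat = best$l, sse = best$sse, residuals = resid,
    trajectory = sim, b0 = b0, l_range = l_range,
    n_obs = nrow(obs), variant = variant
  ), class = "loss_fit")
}

#' @export
print.loss_fit <- function(x, ...) {
  cat(sprintf(
    "<loss_fit> l = %.4g (SSE %.4g over %d observation years, b0 = %g)\n",
    x$l_hat, x$sse, x$n_obs, x$b0))
  invisible(x)
}

#' @exportS3Method
tidy.loss_fit <- function(x, ...) x$residuals

#' @exportS3Method
glance.loss_fit <- function(x, ...) {
  tibble::tibble(l_hat = x$l_hat, sse = x$sse, n_obs = x$n_obs,
                 b0 = x$b0, rmse = sqrt(x$sse / x$n_obs),
                 variant = x$variant)
}

#' Per-reindeer loss relative to per-reindeer intake
#'
#' The mass upended per reindeer-year (`b l`, from `w = b d l`) divided by
#' the mass ingested per reindeer-year (`i`): `b l / i`, linear in the
#' standing biomass.
#'
#' @param trajectory a `lichen_trajectory`.
#' @param params a [model_params()] with `i > 0`; defaults to the
#'   trajectory's own parameters.
#' @return A tibble: `year`, `b`, `loss_intake_ratio`.
#' @export
loss_to_intake_ratio <- function(trajectory, params = attr(trajectory, "params")) {
  if (is.null(params)) params <- model_params()
  if (params$intake_t_per_reindeer_year <= 0) {
    rlang::abort("intake constant must be positive")
  }
  tibble::tibble(
    year = trajectory$year, b = trajectory$b,
    loss_intake_ratio = trajectory$b * params$loss_factor /
      params$intake_t_per_reindeer_year
  )
}
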