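#' Gordon-Taylor parameter set
#'
#' Parameters of the two-component Gordon-Taylor mixing rule for the glass
#' transition of a water-plasticized polymer.
#'
#' @param Tgs glass-transition temperature of the dry matter, degrees C
#' @param Tgw glass-transition temperature of pure water, degrees C;
#'   conventionally fixed at -135
#' @param k dimensionless Gordon-Taylor constant, must be positive
#' @return an object of class `gt_params`
#' @export
gt_params <- function(Tgs, Tgw = -135, k) {
  stopifnot(is.numeric(Tgs), is.numeric(Tgw), is.numeric(k))
  if (k <= 0) stop("Gordon-Taylor constant k must be positive")
  if (Tgs <= Tgw) stop("Tgs must exceed Tgw")
  structure(list(Tgs = Tgs, Tgw = Tgw, k = k), class = "gt_params")
}

#' Gordon-Taylor glass-transition temperature
#'
#' Evaluates Tg(Xw) = (Xs*Tgs + k*Xw*Tgw) / (Xs + k*Xw) with Xs = 1 - Xw,
#' where Xw is the wet-basis mass fraction of water.
#'
#' @param Xw water mass fraction (wet basis), in \[0, 1\]; vectorised
#' @param params a [gt_params()] object
#' @return glass-transition temperature(s), degrees C
#' @examples
#' p <- gt_params(Tgs = 112.4, Tgw = -135, k = 2.4)
#' gt_tg(0.1069, p)
#' @export
gt_tg <- function(Xw, params) {
  stopifnot(inherits(params, "gt_params"))
  if (any(Xw < 0 | Xw > 1)) stop("water mass fraction must lie in [0, 1]")
  Xs <- 1 - Xw
  (Xs * params$Tgs + params$k * Xw * params$Tgw) / (Xs + params$k * Xw)
}

#' Fit the Gordon-Taylor model to Tg-versus-water data
#'
#' Least-squares estimation of (Tgs, k) by Levenberg-Marquardt, with the
#' pure-water glass transition Tgw held fixed at a literature value.
#'
#' @param points data frame with columns `Xw` (wet-basis water mass fraction)
#'   and `Tg` (degrees C)
#' @param Tgw_fixed fixed water glass-transition temperature, degrees C
#' @param init optional named list with starting values `Tgs` and `k`
#' @return list with elements `params` ([gt_params()]), `r_squared`,
#'   `residuals`, and `degenerate` (TRUE when the data carry no water-content
#'   signal and k has collapsed to its lower bound)
#' @export
fit_gt <- function(points, Tgw_fixed = -135, init = NULL) {
  stopifnot(is.data.frame(points), all(c("Xw", "Tg") %in% names(points)))
  if (nrow(points) < 3) stop("at least 3 (Xw, Tg) points are required")
  if (length(unique(points$Xw)) < 2) stop("Xw values must not all be equal")
  if (is.null(init)) {
    init <- list(Tgs = max(points$Tg), k = 1)
  }
  resid_fun <- function(par) {
    p <- gt_params(Tgs = par[["Tgs"]], Tgw = Tgw_fixed, k = par[["k"]])
    points$Tg - gt_tg(points$Xw, p)
  }
  fit <- minpack.lm::nls.lm(
    par = c(Tgs = init$Tgs, k = init$k),
    lower = c(Tgs = Tgw_fixed + 1e-6, k = 1e-8),
    upper = c(Tgs = Inf, k = Inf),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((points$Tg - mean(points$Tg))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  degenerate <- est[["k"]] <= 1e-6
  list(
    params = gt_params(Tgs = est[["Tgs"]], Tgw = Tgw_fixed, k = max(est[["k"]], 1e-8)),
    r_squared = r2,
    residuals = stats::residuals(fit),
    degenerate = degenerate
  )
}

#' Moisture-content value with an explicit basis
#'
#' @param value moisture content, g water per g (of dry matter or of product)
#' @param basis `"dry_matter"` (g water / g dry matter) or `"wet"`
#'   (g water / g product, i.e. a mass fraction)
#' @return object of class `moisture_value`
#' @export
moisture_value <- function(value, basis = c("dry_matter", "wet")) {
  basis <- match.arg(basis)
  if (value < 0) stop("moisture content must be non-negative")
  if (basis == "wet" && value >= 1) stop("wet-basis moisture must be below 1")
  structure(list(value = value, basis = basis), class = "moisture_value")
}

#' Convert moisture content between dry-matter and wet basis
#'
#' wet = dm / (1 + dm); dm = wet / (1 - wet). The round trip is the identity.
#'
#' @param m a [moisture_value()]
#' @param target_basis `"dry_matter"` or `"wet"`
#' @return a [moisture_value()] on the requested basis
#' @export
moisture_convert <- function(m, target_basis = c("dry_matter", "wet")) {
  stopifnot(inherits(m, "moisture_value"))
  target_basis <- match.arg(target_basis)
  if (m$basis == target_basis) return(m)
  value <- if (target_basis == "wet") m$value / (1 + m$value)
           else m$value / (1 - m$value)
  moisture_value(value, target_basis)
}

#' Carbohydrate content by difference
#'
#' Total carbohydrates of a proximate composition, estimated as the residue
#' after moisture, protein, fat and ash.
#'
#' @param moisture_pct,protein_pct,fat_pct,ash_pct percentages in \[0, 100\]
#' @return carbohydrate residue, percent
#' @examples
#' carbohydrate_residue(5.16, 7.02, 0.45, 0.73)  # 86.64
#' @export
carbohydrate_residue <- function(moisture_pct, protein_pct, fat_pct, ash_pct) {
  comps <- c(moisture_pct, protein_pct, fat_pct, ash_pct)
  if (any(comps < 0 | comps > 100)) stop("components must lie in [0, 100]")
  if (sum(comps) > 100) stop("components sum to more than 100%")
  100 - sum(comps)
}
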