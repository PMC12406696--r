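# Monoisotopic atomic masses (Da) and the proton mass used for negative-mode
# deprotonated ions.
MONO_MASS <- c(C = 12, H = 1.0078250319, O = 15.9949146221, P = 30.97376151)
PROTON_MASS <- 1.00727646688

#' Construct an inositol-phosphate species
#'
#' A *myo*-inositol ring carrying phosphate groups on a subset of positions
#' 1-6. The molecular formula is inositol (C6H12O6) plus one HPO3 per
#' phosphate.
#'
#' @param phospho_positions integer subset of 1:6 (may be empty).
#' @return object of class `insp_species` with `positions`, `n_phosphates`,
#'   `name` (e.g. `"Ins(2,4,6)P3"`, `"InsP6"`), `formula` (named element
#'   counts).
#' @export
insp_species <- function(phospho_positions) {
  pos <- sort(unique(as.integer(phospho_positions)))
  if (length(pos) && (any(pos < 1L) || any(pos > 6L)))
    stop("phosphorylation positions must lie in 1..6")
  n <- length(pos)
  name <- if (n == 0L) "Ins"
          else if (n == 6L) "InsP6"
          else if (n == 1L) sprintf("Ins(%d)P", pos)
          else sprintf("Ins(%s)P%d", paste(pos, collapse = ","), n)
  formula <- c(C = 6, H = 12 + n, O = 6 + 3 * n, P = n)
  structure(list(positions = pos, n_phosphates = n, name = name,
                 formula = formula), class = "insp_species")
}

#' @export
print.insp_species <- function(x, ...) {
  cat(x$name, " (C", x$formula["C"], "H", x$formula["H"], "O",
      x$formula["O"], "P", x$formula["P"], ")\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#' @param formula named numeric vector of element counts (C, H, O, P).
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  unknown <- setdiff(names(formula), names(MONO_MASS))
  if (length(unknown))
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  sum(MONO_MASS[names(formula)] * formula)
}

#' Negative-mode ESI m/z of an inositol-phosphate species
#'
#' Deprotonated-ion m/z: `(M - |z| * m_proton) / |z|` with standard
#' monoisotopic atomic masses, matching `[M-H]-`, `[M-2H]2-`, `[M-3H]3-`
#' observation modes.
#'
#' @param species an `insp_species` (or integer vector of phosphate
#'   positions).
#' @param charge negative integer in `-1`, `-2`, `-3`.
#' @param digits optional rounding for reporting; `NULL` returns full
#'   precision.
#' @return m/z value.
#' @export
insp_monoisotopic_mz <- function(species, charge, digits = NULL) {
  if (!inherits(species, "insp_species")) species <- insp_species(species)
  z <- abs(as.integer(charge))
  if (charge == 0 || !(z %in% 1:3))
    stop("charge must be -1, -2 or -3")
  mz <- (monoisotopic_mass(species$formula) - z * PROTON_MASS) / z
  if (!is.null(digits)) mz <- round(mz, digits)
  mz
}

# Default stepwise removal orders by enzyme class. Only the initial-site
# class (3-/5-phytase) and the terminal products are fixed contracts: the
# alkaline beta-propeller enzymes strip alternate phosphates down to
# Ins(2,4,6)P3, while the acid phytases (HAP, CP, PAP) proceed to Ins(2)P.
DEPHOSPHO_ORDER <- list(
  BPP = c(3L, 1L, 5L),
  HAP = c(3L, 4L, 5L, 6L, 1L),
  CP  = c(5L, 4L, 6L, 3L, 1L),
  PAP = c(5L, 6L, 4L, 3L, 1L)
)

#' Simulate stepwise dephosphorylation of an inositol phosphate
#'
#' Applies an enzyme class's removal order to the starting species until the
#' class's terminal product: from InsP6, BPP releases 3 phosphates ending at
#' Ins(2,4,6)P3; the acid phytases release 5 ending at Ins(2)P.
#'
#' @param enzyme_class one of `"BPP"`, `"HAP"`, `"CP"`, `"PAP"`.
#' @param start starting `insp_species`; default InsP6.
#' @param order optional custom removal order (positions, in sequence),
#'   overriding the class default.
#' @return list with `products` (ordered list of `insp_species` after each
#'   step), `terminal`, `phosphates_released`.
#' @export
simulate_dephosphorylation <- function(enzyme_class,
                                       start = insp_species(1:6),
                                       order = NULL) {
  enzyme_class <- match.arg(enzyme_class, PHYTASE_FAMILIES)
  if (!inherits(start, "insp_species")) start <- insp_species(start)
  if (start$n_phosphates < 1L)
    stop("starting species carries no phosphate")
  if (is.null(order)) order <- DEPHOSPHO_ORDER[[enzyme_class]]
  current <- start$positions
  products <- list()
  released <- 0L
  for (p in order) {
    if (!(p %in% current)) next
    current <- setdiff(current, p)
    released <- released + 1L
    products[[length(products) + 1L]] <- insp_species(current)
  }
  terminal <- if (length(products)) products[[length(products)]] else start
  list(products = products, terminal = terminal,
       phosphates_released = released)
}

#' Michaelis-Menten reaction rate
#'
#' `v = Vmax * S / (Km + S)`.
#'
#' @param S substrate concentration (mM), non-negative.
#' @param Km Michaelis constant (mM), positive.
#' @param Vmax maximal rate, positive.
#' @return rate in the units of `Vmax`.
#' @export
mm_rate <- function(S, Km, Vmax) {
  if (Km <= 0 || Vmax <= 0) stop("Km and Vmax must be positive")
  if (any(S < 0)) stop("substrate concentration must be non-negative")
  Vmax * S / (Km + S)
}

#' Fit Michaelis-Menten parameters by the Lineweaver-Burk method
#'
#' Ordinary least squares of `1/v` on `1/S` (the double-reciprocal plot):
#' `Km = slope / intercept`, `Vmax = 1 / intercept`. `kcat` is attached when
#' a molecular mass is supplied (see [kcat_from_vmax()]). A nonlinear
#' least-squares alternative is available in [fit_mm_nls()]; it is never
#' silently substituted.
#'
#' @param S substrate concentrations (mM), all positive.
#' @param v rates, all positive; at least 3 points.
#' @param Mw optional molecular mass (Da) for the kcat conversion.
#' @return object of class `kinetics_fit`: `Km`, `Vmax`, `kcat` (or `NA`),
#'   `Mw`, `r_squared`, `residuals`, `method = "lineweaver-burk"`.
#' @export
fit_lineweaver_burk <- function(S, v, Mw = NA_real_) {
  if (length(S) != length(v)) stop("S and v must align")
  if (length(S) < 3L) stop("need at least 3 points")
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  if (any(v <= 0)) stop("rates must be positive (reciprocal undefined)")
  x <- 1 / S; y <- 1 / v
  fit <- stats::lm(y ~ x)
  intercept <- unname(stats::coef(fit)[1L])
  slope <- unname(stats::coef(fit)[2L])
  if (intercept <= 0)
    warning("non-positive double-reciprocal intercept; ",
            "Km/Vmax estimates unreliable")
  Km <- slope / intercept
  Vmax <- 1 / intercept
  kcat <- if (is.na(Mw)) NA_real_ else kcat_from_vmax(Vmax, Mw)
  structure(list(Km = Km, Vmax = Vmax, kcat = kcat, Mw = Mw,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 residuals = stats::residuals(fit),
                 method = "lineweaver-burk"),
            class = "kinetics_fit")
}

#' Fit Michaelis-Menten parameters by nonlinear least squares
#'
#' Direct fit of `v = Vmax S / (Km + S)` with [stats::nls()], reported as a
#' labelled alternative to the double-reciprocal method.
#'
#' @inheritParams fit_lineweaver_burk
#' @return a `kinetics_fit` with `method = "nls"`.
#' @export
fit_mm_nls <- function(S, v, Mw = NA_real_) {
  if (length(S) < 3L) stop("need at least 3 points")
  start <- list(Vmax = max(v), Km = stats::median(S))
  fit <- stats::nls(v ~ Vmax * S / (Km + S), start = start,
                    control = stats::nls.control(warnOnly = TRUE))
  cf <- stats::coef(fit)
  kcat <- if (is.na(Mw)) NA_real_ else kcat_from_vmax(cf[["Vmax"]], Mw)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((v - mean(v))^2)
  structure(list(Km = cf[["Km"]], Vmax = cf[["Vmax"]], kcat = kcat,
                 Mw = Mw, r_squared = 1 - ss_res / ss_tot,
                 residuals = stats::residuals(fit), method = "nls"),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%s): Km = %.4g mM, Vmax = %.6g",
              x$method, x$Km, x$Vmax))
  if (!is.na(x$kcat))
    cat(sprintf(", kcat = %.6g s^-1 (Mw = %g Da)", x$kcat, x$Mw))
  cat(sprintf("; R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Turnover number from specific activity
#'
#' `kcat = Vmax * Mw / 60000`, converting a specific activity in
#' umol min^-1 mg^-1 and a molecular mass in Da to s^-1 (per total
#' protein).
#'
#' @param Vmax specific activity (umol min^-1 mg^-1), positive.
#' @param Mw molecular mass (Da), positive.
#' @return kcat in s^-1.
#' @export
kcat_from_vmax <- function(Vmax, Mw) {
  if (Vmax <= 0 || Mw <= 0) stop("Vmax and Mw must be positive")
  Vmax * Mw / 60000
}

#' qPCR relative gene abundance from crossing points
#'
#' Ratio of crossing-point (Cp) cycles between the 16S rRNA reference gene
#' and the target gene: `Cp_ref / Cp_target`.
#'
#' @param Cp_ref,Cp_target crossing points in cycles, positive.
#' @return the abundance ratio.
#' @export
qpcr_gene_abundance <- function(Cp_ref, Cp_target) {
  if (any(Cp_ref <= 0) || any(Cp_target <= 0))
    stop("Cp values must be positive")
  Cp_ref / Cp_target
}

#' Phytate degradation rate from a concentration time series
#'
#' Least-squares slope of concentration (uM) against time (days), negated
#' and divided by sample mass: uM day^-1 g^-1. An optional control series
#' (abiotic blank) is fitted the same way and its slope subtracted before
#' normalization. Negative computed rates are clipped to zero with a
#' warning.
#'
#' @param day,concentration numeric vectors (>= 2 timepoints).
#' @param sample_mass mass in grams, positive.
#' @param control optional data frame / list with `day` and `concentration`
#'   for the blank.
#' @return rate in uM per day per gram.
#' @export
phytate_degradation_rate <- function(day, concentration, sample_mass,
                                     control = NULL) {
  if (length(day) < 2L) stop("need at least 2 timepoints")
  if (length(day) != length(concentration)) stop("day and concentration must align")
  if (sample_mass <= 0) stop("sample mass must be positive")
  slope <- unname(stats::coef(stats::lm(concentration ~ day))[2L])
  if (!is.null(control)) {
    cs <- unname(stats::coef(stats::lm(control$concentration ~
                                         control$day))[2L])
    slope <- slope - cs
  }
  rate <- -slope / sample_mass
  if (rate < 0) {
    warning("computed degradation rate was negative; clipped to 0")
    rate <- 0
  }
  rate
}
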