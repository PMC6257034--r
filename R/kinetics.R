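#' Cultivar-level kinetic parameter set
#'
#' Bundle of rate constants (at the reference temperature) and activation
#' energies for the softening model. `kfenz_ref` is the lumped rate
#' constant k_f x k_enz that arises when the initial enzyme level is fixed
#' to zero, making the two factors unidentifiable separately.
#'
#' @param kfenz_ref Lumped softening rate constant at `t_ref` (mol^-1 d^-1).
#' @param kd_ref Enzyme-degradation rate constant at `t_ref` (d^-1).
#' @param E_fenz Activation energy of the lumped softening reaction (kJ/mol).
#' @param E_d Activation energy of enzyme degradation (kJ/mol).
#' @param t_ref Reference temperature (K). Fixed at 295.15 K (22 degC) for
#'   the packaged parameter sets.
#' @param cultivar Optional cultivar label.
#' @return An object of class `kinetic_params`.
#' @seealso [cultivar_params()] for the packaged 'Keitt' and 'Kent' sets.
#' @export
#' @examples
#' kp <- kinetic_params(kfenz_ref = 0.099, kd_ref = 0.219,
#'                      E_fenz = 169.9, E_d = 0.01)
#' arrhenius_rate(kp$kfenz_ref, kp$E_fenz, 293.15)
kinetic_params <- function(kfenz_ref, kd_ref, E_fenz, E_d,
                           t_ref = T_REF_K, cultivar = NA_character_) {
  stopifnot(is.numeric(kfenz_ref), is.numeric(kd_ref),
            is.numeric(E_fenz), is.numeric(E_d), length(kfenz_ref) == 1L)
  if (kfenz_ref <= 0) stop("'kfenz_ref' must be > 0", call. = FALSE)
  if (kd_ref <= 0) stop("'kd_ref' must be > 0", call. = FALSE)
  if (E_fenz < 0 || E_d < 0)
    stop("activation energies must be >= 0", call. = FALSE)
  if (!isTRUE(all.equal(t_ref, T_REF_K)))
    stop("'t_ref' is fixed at 295.15 K for this model", call. = FALSE)
  structure(list(kfenz_ref = kfenz_ref, kd_ref = kd_ref,
                 E_fenz = E_fenz, E_d = E_d, t_ref = t_ref,
                 cultivar = cultivar),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameter set",
      if (!is.na(x$cultivar)) paste0("('", x$cultivar, "')"), "\n")
  cat(sprintf("  kfenz_ref = %g mol^-1 d^-1, kd_ref = %g d^-1 (at %.2f K)\n",
              x$kfenz_ref, x$kd_ref, x$t_ref))
  cat(sprintf("  E_fenz = %g kJ/mol, E_d = %g kJ/mol\n", x$E_fenz, x$E_d))
  invisible(x)
}

#' Packaged kinetic parameters for 'Keitt' and 'Kent' mangoes
#'
#' Reads the cultivar-level rate constants and activation energies shipped
#' with the package. The 'Kent' set has `kfenz_ref` fixed to 1 (only the
#' product k_fenz x Eth, the ethylene factor, was identifiable for that
#' cultivar).
#'
#' @param cultivar `"Keitt"` or `"Kent"` (case-insensitive).
#' @return A [kinetic_params()] object.
#' @export
#' @examples
#' cultivar_params("Keitt")
cultivar_params <- function(cultivar = c("Keitt", "Kent")) {
  if (length(cultivar) == 1L)
    cultivar <- c(Keitt = "Keitt", Kent = "Kent")[
      match(tolower(cultivar), c("keitt", "kent"))]
  cultivar <- match.arg(cultivar)
  path <- system.file("extdata", "kinetic_params.yml", package = "mangofirm",
                      mustWork = TRUE)
  y <- yaml::read_yaml(path)
  p <- y[[cultivar]]
  kinetic_params(kfenz_ref = p$kfenz_ref, kd_ref = p$kd_ref,
                 E_fenz = p$E_fenz, E_d = p$E_d,
                 t_ref = y$t_ref_k, cultivar = cultivar)
}

#' Arrhenius temperature scaling of a rate constant
#'
#' Scales a rate constant from the reference temperature (295.15 K) to an
#' arbitrary temperature: `k(T) = k_ref * exp((E * 1000 / R) *
#' (1/T_ref - 1/T))` with R = 8.314 J/(mol K). The factor 1000 converts
#' the activation energy from kJ/mol to J/mol.
#'
#' @param k_ref Rate constant at `t_ref` (> 0).
#' @param E Activation energy (kJ/mol, >= 0). `E = 0` gives a
#'   temperature-independent rate.
#' @param temp_k Temperature in Kelvin (> 0); vectorised.
#' @param t_ref Reference temperature (K), default 295.15.
#' @return Rate constant(s) at `temp_k`.
#' @export
#' @examples
#' arrhenius_rate(0.099, 169.9, 293.15)  # Keitt k_fenz at 20 degC
arrhenius_rate <- function(k_ref, E, temp_k, t_ref = T_REF_K) {
  if (!is.numeric(k_ref) || any(k_ref <= 0))
    stop("'k_ref' must be a positive number", call. = FALSE)
  if (!is.numeric(temp_k) || any(temp_k <= 0))
    stop("'temp_k' must be positive (Kelvin)", call. = FALSE)
  if (any(E < 0)) stop("'E' must be >= 0 (kJ/mol)", call. = FALSE)
  k_ref * exp((E * 1000 / GAS_CONSTANT) * (1 / t_ref - 1 / temp_k))
}

#' Per-fruit state of the softening model
#'
#' @param F0 Initial firmness (FI units); must exceed `ffix`.
#' @param eth Ethylene driver for this fruit or its batch (arbitrary
#'   units, >= 0).
#' @param ffix Residual asymptotic firmness (FI units, >= 0).
#' @param enz0 Initial enzyme level, in the lumped units `k_f x Enz`
#'   (arbitrary, >= 0). Default 0: ripening is assumed inhibited on the
#'   tree (tree factor) or by chilling during reefer transport.
#' @return An object of class `fruit_state`.
#' @export
fruit_state <- function(F0, eth, ffix = 0, enz0 = 0) {
  stopifnot(is.numeric(F0), is.numeric(eth), is.numeric(ffix),
            is.numeric(enz0))
  if (ffix < 0) stop("'ffix' must be >= 0", call. = FALSE)
  if (F0 <= ffix) stop("'F0' must exceed 'ffix'", call. = FALSE)
  if (eth < 0) stop("'eth' must be >= 0", call. = FALSE)
  if (enz0 < 0) stop("'enz0' must be >= 0", call. = FALSE)
  structure(list(F0 = F0, eth = eth, ffix = ffix, enz0 = enz0),
            class = "fruit_state")
}

celsius_to_kelvin <- function(temp_c) temp_c + 273.15
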