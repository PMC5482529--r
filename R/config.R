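# Declarative run configuration shared by the command-line interface and
# the higher-level pipeline helpers.

.pepgel_defaults <- function() {
  list(
    q_units = "nm",                    # "nm" (nm^-1) or "ang" (Angstrom^-1)
    tan_delta_threshold = 1,           # gel criterion on max tan(delta)
    gprime_slope_threshold = 0.2,      # gel criterion on d logG'/d logw
    aicc_tie_margin = 2,               # parsimony margin for model selection
    sans_background = FALSE,           # additive constant background term
    nmr_gelator_window = c(6.8, 8.6),  # aromatic gelator peak set, ppm
    nmr_std_window = c(-0.3, 0.3),     # DSS reference singlet, ppm
    nmr_molar_mass = c(gelator = 700, standard = 218.32),
    period_significance_factor = 10,   # spectral peak / median power
    sigma_scale = 0.01,                # sqrt(I) surrogate scale
    seed = 1L,
    out_dir = "."
  )
}

#' Build a validated run configuration
#'
#' Returns the default configuration with any supplied overrides applied.
#' Unknown keys are rejected; thresholds must be positive. The default
#' molar masses cover the gelator molecule (a ~0.7 kg/mol tripeptide
#' amphiphile; synthetic default, override for other gelators) and the DSS
#' sodium salt (218.32 g/mol).
#'
#' @param ... named overrides of the default keys.
#' @return named list of class `pepgel_config`.
#' @export
pepgel_config <- function(...) {
  cfg <- .pepgel_defaults()
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots)))))
    stop_input("all config entries must be named")
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!cfg$q_units %in% c("nm", "ang")) stop_input("q_units must be nm or ang")
  for (k in c("tan_delta_threshold", "gprime_slope_threshold",
              "aicc_tie_margin", "period_significance_factor", "sigma_scale"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop_input(k, " must be a positive number")
  structure(cfg, class = "pepgel_config")
}
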