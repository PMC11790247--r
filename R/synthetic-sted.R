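#' Specification of a synthetic STED-scale intensity profile
#'
#' Describes a 1-D line profile across the membrane-associated periodic
#' skeleton: a carrier envelope modulated by a cosine of the ring period
#' (~190 nm for spectrin/ankyrin in the AIS), plus fractional Gaussian noise.
#'
#' @param period ring period in nm (default 190).
#' @param region_length profile length in nm; analysis-grade profiles are
#'   >= 2000 nm (default 2000).
#' @param sample_spacing nm between samples (default 10; must satisfy
#'   Nyquist, i.e. <= period/4).
#' @param envelope `"plateau"` (flat) or `"gaussian"` (bump over the region).
#' @param modulation_depth fractional modulation 0–1 (default 0.8).
#' @param noise_sd Gaussian noise SD as a fraction of the envelope amplitude.
#' @return an object of class `sted_profile_spec`.
#' @export
sted_profile_spec <- function(period = 190, region_length = 2000,
                              sample_spacing = 10,
                              envelope = c("plateau", "gaussian"),
                              modulation_depth = 0.8, noise_sd = 0) {
  envelope <- match.arg(envelope)
  if (period <= 0 || region_length <= 0 || sample_spacing <= 0)
    ais_error("period, region_length and sample_spacing must be > 0", "ais_bad_input")
  if (sample_spacing > period / 4)
    ais_error("sample_spacing exceeds period/4 (undersampled)", "ais_undersampled")
  if (modulation_depth < 0 || modulation_depth > 1)
    ais_error("modulation_depth must be in [0, 1]", "ais_bad_input")
  if (noise_sd < 0) ais_error("noise_sd must be >= 0", "ais_bad_input")
  structure(list(period = period, region_length = region_length,
                 sample_spacing = sample_spacing, envelope = envelope,
                 modulation_depth = modulation_depth, noise_sd = noise_sd),
            class = "sted_profile_spec")
}

#' Generate a synthetic STED intensity profile
#'
#' Noiseless output is `envelope(x) * (1 + modulation_depth *
#' cos(2*pi*x/period))`; noise adds `N(0, noise_sd)` per sample (fraction of
#' the unit envelope). Intensities are clipped at zero.
#'
#' @param spec a [sted_profile_spec()].
#' @param seed integer seed for the noise draw.
#' @return list with `positions` (nm), `intensity`, `spacing` (nm) and `spec`.
#' @export
generate_sted_profile <- function(spec, seed = NULL) {
  if (!inherits(spec, "sted_profile_spec"))
    ais_error("spec must be a sted_profile_spec", "ais_bad_input")
  x <- seq(0, spec$region_length, by = spec$sample_spacing)
  env <- switch(spec$envelope,
                plateau = rep(1, length(x)),
                gaussian = exp(-(x - spec$region_length / 2)^2 /
                                 (2 * (spec$region_length / 4)^2)))
  v <- env * (1 + spec$modulation_depth * cos(2 * pi * x / spec$period))
  if (spec$noise_sd > 0)
    v <- with_seed(seed, v + rnorm(length(v), 0, spec$noise_sd))
  v[v < 0] <- 0
  list(positions = x, intensity = v, spacing = spec$sample_spacing, spec = spec)
}
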