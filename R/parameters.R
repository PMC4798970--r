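# Kinetic parameter containers and randomized sampling.

.kinetic_names <- c("d_K", "n", "d", "gamma", "d_I", "p", "a", "kappa",
                    "k_I", "d_RI", "k_on_I", "k_on0_I", "k_off_I", "k_off0_I",
                    "k_on_A", "k_on0_A", "k_off_A", "k_off0_A",
                    "d_RA", "k_A", "d_A")

#' Kinetic parameters of the NF-kB network model
#'
#' The 21 normalized rates of the two-feedback model: IKK inactivation
#' (\code{d_K}), the Hill exponent \code{n} and the A20-modulated activation
#' term, complex dissociation \code{d}, IkBa degradation in the complex
#' (\code{gamma * d_I}) and free (\code{d_I}), IKK-driven complex degradation
#' \code{p} (with factor \code{kappa} for free IkBa), association \code{a},
#' IkBa translation \code{k_I} and mRNA turnover \code{d_RI}, telegraph-model
#' gene switching rates for the IkBa and A20 genes
#' (\code{k_on_*, k_on0_*, k_off_*, k_off0_*}), A20 mRNA turnover
#' \code{d_RA}, translation \code{k_A} and degradation \code{d_A}.
#' All rates are h^-1; \code{n} is adimensional.
#'
#' When \code{repressor_active} is \code{FALSE}, IkBa does not act as a
#' transcriptional repressor: the \code{k_off_I * I}, \code{k_off_A * I}
#' (and, for regulated genes, \code{k_off_G * I}) terms are dropped from the
#' dynamics while the basal \code{k_off0_*} inactivation remains.
#'
#' @param ... named rates overriding the calibrated baseline
#'   (see [default_parameters()]).
#' @param repressor_active logical flag for the IkBa-repressor feedback arm.
#' @return an object of class \code{kinetic_params} (a named list).
#' @export
kinetic_params <- function(..., repressor_active = TRUE) {
  p <- default_parameters()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .kinetic_names)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  vals <- unlist(p[.kinetic_names])
  if (any(!is.finite(vals)) || any(vals < 0)) stop("all rates must be finite and >= 0")
  if (p$n < 1) stop("Hill exponent n must be >= 1")
  structure(c(p, list(repressor_active = isTRUE(repressor_active))),
            class = "kinetic_params")
}

#' Calibrated baseline parameter set
#'
#' A documented baseline for the normalized model, calibrated so that under
#' constant stimulation S = 2 h^-1 (10 ng/ml TNF-alpha) the response is a
#' damped oscillation with a first nuclear peak within ~30 min and a dominant
#' inter-peak interval close to the 90 min natural period. The calibration
#' search is reproducible with \code{scripts/calibrate_baseline.R}.
#'
#' @return named list of the 21 rates (h^-1; \code{n} adimensional).
#' @export
default_parameters <- function() {
  list(
    d_K   = 9.64,   # IKK spontaneous inactivation
    n     = 1,      # Hill exponent of A20 inhibition of IKK activation
    d     = 0.163,  # spontaneous complex dissociation
    gamma = 0.514,  # relative IkBa degradation rate within the complex
    d_I   = 0.806,  # free IkBa degradation
    p     = 25.1,   # IKK-driven IkBa degradation in the complex
    a     = 173,    # NF-kB:IkBa association
    kappa = 0.218,  # IKK-driven degradation factor for free IkBa
    k_I   = 13.3,   # IkBa translation (lumped with transcription scale)
    d_RI  = 2.41,   # IkBa mRNA turnover
    k_on_I   = 4.68,    k_on0_I = 0.0908,
    k_off_I  = 11.8,    k_off0_I = 0.189,
    k_on_A   = 4.52,    k_on0_A = 0.00948,
    k_off_A  = 19.6,    k_off0_A = 0.308,
    d_RA  = 17.9,   # A20 mRNA turnover (effective, lumps fast processing)
    k_A   = 1.47,   # A20 translation
    d_A   = 1.28    # A20 protein degradation
  )
}

#' Default per-parameter uncertainty degrees
#'
#' Each parameter carries an uncertainty degree \code{D} in \code{[0, 1]}:
#' randomization multiplies the rate by \code{10^u}, \code{u ~ U(-D, D)}.
#' Manually fitted and feedback-summary parameters (the Hill exponent, the
#' A20 module, gene on/off switching) get \code{D = 1}; degradation and
#' binding rates anchored in the literature get \code{D = 0.3}.
#'
#' @return named numeric vector of degrees over the 21 parameters.
#' @export
default_degrees <- function() {
  D <- c(d_K = 0.3, n = 1, d = 0.3, gamma = 0.3, d_I = 0.3, p = 0.3, a = 0.3,
         kappa = 0.3, k_I = 0.3, d_RI = 0.3,
         k_on_I = 1, k_on0_I = 1, k_off_I = 1, k_off0_I = 1,
         k_on_A = 1, k_on0_A = 1, k_off_A = 1, k_off0_A = 1,
         d_RA = 1, k_A = 1, d_A = 1)
  D[.kinetic_names]
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> 21 normalized rates (h^-1), repressor_active =",
      x$repressor_active, "\n")
  print(round(unlist(x[.kinetic_names]), 4))
  invisible(x)
}

#' Telegraph-model parameters for an NF-kB regulated gene
#'
#' On-rate proportional to nuclear NF-kB (\code{k_on_G * N + k_on0_G}),
#' off-rate optionally proportional to free IkBa
#' (\code{k_off_G * I + k_off0_G}), and mature-mRNA turnover \code{d_R_G}.
#'
#' @param k_on_G,k_on0_G,k_off_G,k_off0_G,d_R_G non-negative rates (h^-1).
#' @return an object of class \code{gene_params}.
#' @export
gene_params <- function(k_on_G = 5, k_on0_G = 0.03,
                        k_off_G = 4, k_off0_G = 0.35, d_R_G = 1.4) {
  vals <- c(k_on_G = k_on_G, k_on0_G = k_on0_G, k_off_G = k_off_G,
            k_off0_G = k_off0_G, d_R_G = d_R_G)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("gene rates must be finite and >= 0")
  structure(as.list(vals), class = "gene_params")
}

#' Log-uniform parameter prior from uncertainty degrees
#'
#' @param base a \code{kinetic_params} baseline.
#' @param degrees named vector of per-parameter degrees \code{D} in [0, 1];
#'   defaults to [default_degrees()].
#' @return an object of class \code{parameter_prior}.
#' @export
parameter_prior <- function(base = kinetic_params(), degrees = default_degrees()) {
  if (!inherits(base, "kinetic_params")) stop("base must be kinetic_params")
  if (is.null(names(degrees)) || !all(names(degrees) %in% .kinetic_names))
    stop("degrees must be named after kinetic parameters")
  D <- rep(0, length(.kinetic_names)); names(D) <- .kinetic_names
  D[names(degrees)] <- degrees
  if (any(D < 0 | D > 1)) stop("uncertainty degrees must lie in [0, 1]")
  structure(list(base = base, degrees = D), class = "parameter_prior")
}

#' Draw a randomized parameter set
#'
#' Each rate of the baseline is multiplied by an independent factor
#' \code{10^u} with \code{u ~ Uniform(-D, D)} for its uncertainty degree
#' \code{D}, so a degree of 1 spans one order of magnitude either way.
#' The Hill exponent \code{n} is randomized like any other parameter
#' (not rounded) but floored at 1.
#'
#' @param prior a \code{parameter_prior}.
#' @param seed optional integer seed for a reproducible draw; if \code{NULL}
#'   the current RNG stream is used.
#' @return a \code{kinetic_params} draw.
#' @export
randomize_parameters <- function(prior, seed = NULL) {
  if (!inherits(prior, "parameter_prior")) stop("prior must be a parameter_prior")
  if (!is.null(seed)) set.seed(seed)
  D <- prior$degrees
  u <- stats::runif(length(D), -D, D)
  vals <- unlist(prior$base[.kinetic_names]) * 10^u
  vals["n"] <- max(1, vals["n"])
  out <- prior$base
  out[.kinetic_names] <- as.list(vals)
  out
}
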