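#' Load the default physiological muscle parameter table
#'
#' Per monitored muscle: flexor/extensor role, maximum voluntary force
#' (mean and SD, N), wrist moment arm at neutral position (mean and SD, m,
#' flexors positive / extensors negative), physiological cross-sectional
#' area (cm²), and the deep/intermediate muscles the surface channel is
#' assumed to represent with their pooled PCSA. The derived column
#' `sigma_pcsa_cm2` is the channel's own PCSA plus the represented PCSA.
#'
#' Values are editable defaults set from standard anatomy literature ranges;
#' ship your own CSV with the same columns to override.
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return A data.frame with one row per muscle, in canonical channel order.
#' @export
muscle_table <- function(path = system.file("extdata",
                                            "muscle_parameters.csv",
                                            package = "semgtorque")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("muscle", "role", "fmax_mean_N", "fmax_sd_N", "ma_mean_m",
           "ma_sd_m", "pcsa_cm2", "represented_pcsa_cm2")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("muscle table lacks columns: ", paste(missing, collapse = ", "))
  tab$sigma_pcsa_cm2 <- tab$pcsa_cm2 + tab$represented_pcsa_cm2
  ok_sign <- ifelse(tab$role == "flexor", tab$ma_mean_m > 0, tab$ma_mean_m < 0)
  if (!all(ok_sign))
    stop("moment arm signs must be positive for flexors, negative for extensors")
  stopifnot(all(tab$fmax_mean_N > 0), all(tab$pcsa_cm2 > 0))
  tab
}

#' Activation dynamics parameters
#'
#' Shared (across muscles) parameters of the discrete second-order recursive
#' activation filter and the nonlinear shaping function: recursive
#' coefficients `C1`, `C2` (each with absolute value below 1 for stability),
#' electromechanical delay `d_ms` (10–100 ms for skeletal muscle), and the
#' nonlinear shape factor `A` in \[-3, 0\] (0 = linear). Derived
#' coefficients: beta1 = C1 + C2, beta2 = C1·C2, alpha = 1 + beta1 + beta2,
#' which forces unit DC gain so sustained full excitation maps to full
#' activation.
#'
#' @param A Nonlinear shape factor, in \[-3, 0\].
#' @param C1,C2 Recursive coefficients, |C1| < 1 and |C2| < 1.
#' @param d_ms Electromechanical delay in milliseconds, in \[10, 100\].
#' @return A list of class `activation_params` with derived `alpha`,
#'   `beta1`, `beta2`.
#' @export
activation_params <- function(A = -1, C1 = 0.5, C2 = -0.2, d_ms = 40) {
  if (!(A >= -3 && A <= 0)) stop("A must lie in [-3, 0]")
  if (!(abs(C1) < 1 && abs(C2) < 1))
    stop("unstable recursive filter: |C1| and |C2| must be below 1")
  if (!(d_ms >= 10 && d_ms <= 100))
    stop("d_ms must lie in [10, 100] ms")
  beta1 <- C1 + C2
  beta2 <- C1 * C2
  structure(list(A = A, C1 = C1, C2 = C2, d_ms = d_ms,
                 beta1 = beta1, beta2 = beta2,
                 alpha = 1 + beta1 + beta2),
            class = "activation_params")
}

#' Per-muscle physiology for the torque model
#'
#' @param name Muscle label.
#' @param fmax_N Maximum voluntary force, N (> 0).
#' @param ma_m Moment arm at neutral wrist, m; positive for flexors,
#'   negative for extensors.
#' @param pcsa_cm2 Physiological cross-sectional area, cm².
#' @param sigma_pcsa_cm2 Own PCSA plus PCSA of represented deep muscles;
#'   at least `pcsa_cm2`.
#' @param role `"flexor"` or `"extensor"`.
#' @return A list of class `muscle_physiology`.
#' @export
muscle_physiology <- function(name, fmax_N, ma_m, pcsa_cm2,
                              sigma_pcsa_cm2 = pcsa_cm2,
                              role = if (ma_m >= 0) "flexor" else "extensor") {
  stopifnot(fmax_N > 0, pcsa_cm2 > 0, sigma_pcsa_cm2 >= pcsa_cm2)
  role <- match.arg(role, c("flexor", "extensor"))
  if ((role == "flexor") != (ma_m > 0))
    stop("moment arm sign inconsistent with role for ", name)
  structure(list(name = name, fmax_N = fmax_N, ma_m = ma_m,
                 pcsa_cm2 = pcsa_cm2, sigma_pcsa_cm2 = sigma_pcsa_cm2,
                 role = role),
            class = "muscle_physiology")
}

#' Full parameter set of the physiological torque model
#'
#' @param activation An [activation_params()] object, shared across muscles.
#' @param muscles List of [muscle_physiology()] objects, ordered to match the
#'   channel order of the training data.
#' @return A list of class `pbm_parameters`.
#' @export
pbm_parameters <- function(activation, muscles) {
  stopifnot(inherits(activation, "activation_params"))
  if (!length(muscles)) stop("at least one muscle required")
  lapply(muscles, function(m) stopifnot(inherits(m, "muscle_physiology")))
  structure(list(activation = activation, muscles = muscles),
            class = "pbm_parameters")
}

# pbm_parameters built from (a subset of) the physiological table, using the
# mean Fmax / moment-arm values.
pbm_parameters_from_table <- function(tab, activation = activation_params(),
                                      channels = tab$muscle,
                                      sigma_pcsa = NULL) {
  rows <- match(channels, tab$muscle)
  if (anyNA(rows)) stop("unknown channels: ",
                        paste(channels[is.na(rows)], collapse = ", "))
  muscles <- lapply(seq_along(rows), function(i) {
    r <- tab[rows[i], ]
    sp <- if (is.null(sigma_pcsa)) r$sigma_pcsa_cm2 else sigma_pcsa[i]
    muscle_physiology(r$muscle, r$fmax_mean_N, r$ma_mean_m, r$pcsa_cm2,
                      max(sp, r$pcsa_cm2), r$role)
  })
  pbm_parameters(activation, muscles)
}

#' PCSA redistribution for reduced channel sets
#'
#' When fewer channels are recorded, the pooled PCSA of unrecorded muscles
#' is reassigned so calibrated forces stay within physiological bounds: each
#' retained flexor receives an equal share of the pooled SigmaPCSA of the
#' dropped flexors (half each for the two primary flexors; the full flexor
#' pool for a single flexor), and likewise for extensors (a third each for
#' the three primary extensors). With all channels present the table values
#' are returned unchanged.
#'
#' @param tab Physiological table ([muscle_table()]).
#' @param channels Retained channel names (subset of `tab$muscle`), needing
#'   at least one flexor and one extensor.
#' @return Numeric vector of redistributed SigmaPCSA values, one per
#'   retained channel.
#' @export
redistribute_sigma_pcsa <- function(tab, channels) {
  rows <- tab[match(channels, tab$muscle), ]
  if (anyNA(rows$muscle)) stop("unknown channels")
  roles <- rows$role
  sigma <- rows$sigma_pcsa_cm2
  if (length(channels) == nrow(tab)) return(sigma)
  for (role in c("flexor", "extensor")) {
    in_role <- roles == role
    if (!any(in_role)) stop("channel set lacks a ", role)
    out_rows <- tab$role == role & !(tab$muscle %in% channels)
    pooled <- sum(tab$sigma_pcsa_cm2[out_rows])
    sigma[in_role] <- sigma[in_role] + pooled / sum(in_role)
  }
  sigma
}
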