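#' Gas constant, J mol^-1 K^-1
#' @keywords internal
.R_GAS <- 8.314

#' Rewrite a chain-length baseline as a power-law rate equation
#'
#' Exponentiating \eqn{\ln(k_f) = a_0 + a_1 \ln L} gives the rate law
#' \eqn{k_f = c_0 L^{a_1}} with pre-exponential factor
#' \eqn{c_0 = \exp(a_0)} (units \eqn{s^{-1}}), the form that connects the
#' empirical fit to transition-state-theory pictures of folding.
#'
#' @param model A [LogLinearModel-class].
#' @return List with `c0` (s^-1), `exponent` (= a1) and `sourceModel`
#'   (the training label).
#' @examples
#' toRateLaw(LogLinearModel(30.788, -5.985, 52))$c0   # ~2.4e13 s^-1
#' @export
toRateLaw <- function(model) {
    stopifnot(is(model, "LogLinearModel"))
    list(c0 = exp(model@a0), exponent = model@a1,
         sourceModel = model@trainingName)
}

#' Predicted folding time from a chain-length baseline
#'
#' The reciprocal of the predicted rate: \eqn{t = 1/k_f =
#' c_0^{-1} L^{-a_1}} seconds. Strictly increasing in `L` when the slope is
#' negative.
#'
#' @param model A [LogLinearModel-class].
#' @param L Chain length(s) in residues, \eqn{\ge 1}.
#' @return Folding time(s) in seconds.
#' @export
foldingTime <- function(model, L) {
    1 / exp(predict(model, L))
}

#' Transition-state-theory folding time
#'
#' \eqn{t = \tau \exp(\Delta G^\#/(R T))}: the elementary time \eqn{\tau}
#' (the time to add one residue to growing secondary structure, of order
#' 1-10 ns) scaled up by the Boltzmann factor of the free-energy barrier.
#'
#' @param deltaG Free-energy barrier \eqn{\Delta G^\#} in J mol^-1.
#' @param T Temperature in kelvin (> 0).
#' @param tau Elementary time in seconds (> 0).
#' @return Folding time in seconds.
#' @examples
#' tstTime(deltaG = 8.314 * 298 * log(1e6), T = 298, tau = 1e-9)  # 1 ms
#' @export
tstTime <- function(deltaG, T, tau) {
    stopifnot(T > 0, tau > 0)
    tau * exp(deltaG / (.R_GAS * T))
}

#' Estimated number of optimally placed secondary-structure elements
#'
#' Two literature estimators for the number \eqn{N} of secondary-structure
#' elements that must be positioned during folding of a chain of length
#' \eqn{L}: an upper estimate \eqn{N = L^{2/3}/3} and an alternative linear
#' estimate \eqn{N = L/15}. At \eqn{L = 100} these give about 7.2 and 6.7
#' elements respectively.
#'
#' @param L Chain length(s) in residues, \eqn{\ge 1}.
#' @param method `"two-thirds-power"` for \eqn{L^{2/3}/3} or `"linear-15"`
#'   for \eqn{L/15}.
#' @return Estimated element count (real-valued).
#' @examples
#' nSecondaryElements(100, "two-thirds-power")
#' nSecondaryElements(100, "linear-15")
#' @export
nSecondaryElements <- function(L, method = c("two-thirds-power",
                                             "linear-15")) {
    method <- match.arg(method)
    L <- as.numeric(L)
    if (any(L < 1)) stop("domain error: L must be >= 1")
    switch(method,
           "two-thirds-power" = L^(2 / 3) / 3,
           "linear-15" = L / 15)
}

#' Scaling-law folding time
#'
#' \eqn{t \sim \tau_s L^N}, equivalently \eqn{\tau_s \exp(N \ln L)}, where
#' \eqn{\tau_s} is the characteristic secondary-structure rearrangement
#' time and \eqn{N} the number of elements to position. The two algebraic
#' forms are identities of each other; both are computed and must agree to
#' machine precision.
#'
#' @param tauS Rearrangement time \eqn{\tau_s} in seconds (> 0).
#' @param N Number of secondary-structure elements (> 0 real).
#' @param L Chain length(s) in residues, \eqn{\ge 1}.
#' @return Folding time(s) in seconds.
#' @export
scalingTime <- function(tauS, N, L) {
    stopifnot(tauS > 0, N >= 0)
    L <- as.numeric(L)
    if (any(L < 1)) stop("domain error: L must be >= 1")
    t1 <- tauS * L^N
    t2 <- tauS * exp(N * log(L))
    stopifnot(all(abs(t1 - t2) <= 1e-12 * pmax(t1, t2)))
    t1
}

#' Theory-consistency summary over a set of chain-length models
#'
#' Collects, per model, the power-law exponent magnitude \eqn{-a_1} and the
#' pre-exponential factor \eqn{c_0 = \exp(a_0)}, plus the mean intercept,
#' mean \eqn{c_0}, and the min/max of \eqn{-a_1} rounded to one decimal --
#' the quantities compared against folding theory, where \eqn{c_0} is
#' expected near the per-residue attempt frequency (~1e13 s^-1) and the
#' exponent near the secondary-structure-element estimates of
#' [nSecondaryElements()].
#'
#' @param models A list of [LogLinearModel-class] objects (or a single one).
#' @return List with `perModel` (data.frame: `model`, `a0`, `a1`, `negA1`,
#'   `c0`), `meanA0`, `meanC0`, and `negA1Range` (1-decimal rounded
#'   `c(min, max)` of \eqn{-a_1}).
#' @export
theoryConsistency <- function(models) {
    if (is(models, "LogLinearModel")) models <- list(models)
    stopifnot(length(models) >= 1L,
              all(vapply(models, is, TRUE, "LogLinearModel")))
    nm <- names(models)
    if (is.null(nm)) nm <- vapply(models, function(m) m@trainingName, "")
    per <- data.frame(
        model = nm,
        a0 = vapply(models, function(m) m@a0, 0),
        a1 = vapply(models, function(m) m@a1, 0),
        stringsAsFactors = FALSE)
    per$negA1 <- -per$a1
    per$c0 <- exp(per$a0)
    list(perModel = per,
         meanA0 = mean(per$a0),
         meanC0 = exp(mean(per$a0)),
         negA1Range = round(range(per$negA1), 1L))
}
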