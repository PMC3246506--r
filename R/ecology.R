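# Reproductive-output allocation and density-dependent fitness.

#' Reproductive output from a response array
#'
#' Allocates each individual's maximum reproductive output phi over niches in
#' proportion to the squared response relative to the summed response:
#' `e_k = phi * psi_k^2 / sum_l psi_l`.  The squared numerator makes output
#' depend on both the relative and the absolute response, so every binary
#' response array (specialist or generalist alike) attains the full total phi
#' while intermediate responses are penalised — the selection pressure toward
#' bimodal (0/1) niche responses.  A fully unresponsive array (all psi = 0)
#' yields zero output.
#'
#' @param psi numeric matrix of responses (individuals x niches), or one
#'   response vector.
#' @param phi maximum reproductive output (default 3).
#' @return numeric matrix `e` of per-niche reproductive output, same shape.
#' @examples
#' reproductiveOutput(c(1, 0, 0, 0))      # specialist: (3, 0, 0, 0)
#' reproductiveOutput(c(1, 1, 1, 1))      # generalist: total still 3
#' reproductiveOutput(c(0.5, 0.5, 0.5, 0.5))  # intermediate: total 1.5
#' @export
reproductiveOutput <- function(psi, phi = 3) {
  stopifnot(phi > 0)
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = 1)
  s <- rowSums(psi)
  e <- phi * psi^2 / ifelse(s > 0, s, 1)
  e[s == 0, ] <- 0
  e
}

#' Total reproductive output per niche
#'
#' Column sums of the population's reproductive-output matrix: the total
#' pre-competition recruit load `E_k = sum_i e_{k,i}` entering the
#' density-dependent discount.
#'
#' @param e numeric matrix of per-individual reproductive outputs
#'   (individuals x niches).
#' @return numeric vector E of per-niche totals.
#' @export
nicheTotals <- function(e) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1)
  if (nrow(e) < 1) stop("at least one individual is required")
  colSums(e)
}

#' Density-dependent fitness
#'
#' Discounts each niche's contribution by a Hill-type competition function:
#' `f_i = sum_k e_{k,i} / (1 + (E_k / (eps * N_k))^a)`.
#' The discount is exactly 1/2 when the niche load E_k equals eps * N_k (the
#' half-saturation density in proportion to the carrying capacity) and the
#' exponent a sets how abruptly density dependence switches on around that
#' level.  An individual's own output is included in E_k.
#'
#' @param e numeric matrix of per-individual reproductive outputs
#'   (individuals x niches) or one individual's output vector.
#' @param E numeric vector of niche totals (from [nicheTotals()]); must be
#'   consistent with the population containing the individuals.
#' @param env a [SimEnvironment-class] supplying the carrying capacities N_k.
#' @param params an [EcologyParams-class] supplying eps and the abruptness a.
#' @return numeric vector of fitness values, one per individual, each in
#'   `[0, sum_k e_{k,i}]`.
#' @examples
#' env <- simEnvironment()
#' e <- reproductiveOutput(matrix(rep(c(1, 0, 0, 0), each = 100), 100))
#' fitnessValues(e, nicheTotals(e), env)[1]  # ~1.91 at E_1 = 300
#' @export
fitnessValues <- function(e, E, env = simEnvironment(),
                          params = ecologyParams()) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1)
  N <- resourceValues(env)
  stopifnot(length(E) == ncol(e), length(N) == ncol(e))
  if (any(N <= 0)) stop("all carrying capacities N_k must be > 0")
  discount <- 1 / (1 + (E / (params@eps * N))^params@abruptness)
  as.vector(e %*% discount)
}
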