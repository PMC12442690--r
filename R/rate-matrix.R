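#' @include AllClasses.R
NULL

#' First-order rate matrix of an exchange model
#'
#' Builds the S x S rate matrix K from the pairwise exchange rates using the
#' detailed-balance convention: for an edge between states i and j with total
#' exchange rate \code{kex_ij}, the directional rate constants are
#' \deqn{k_{i \to j} = kex_{ij} \, p_j / (p_i + p_j), \qquad
#'       k_{j \to i} = kex_{ij} \, p_i / (p_i + p_j),}
#' so that \eqn{p_i k_{i\to j} = p_j k_{j \to i}} on every edge. Off-diagonal
#' entry \code{K[j, i]} is \eqn{k_{i \to j}}; diagonals are minus the column
#' sums, hence columns sum to zero and \code{K %*% populations = 0}
#' (stationarity).
#'
#' @param model an [ExchangeModel-class].
#' @return S x S numeric matrix (s^-1) with dimnames from the state labels.
#' @examples
#' m <- exchangeModel(
#'   states = data.frame(label = c("N", "I"), population = c(0.497/0.503, 0.006/0.503),
#'                       shift_ppm = 0, R1 = 1, R2 = 10),
#'   rates = data.frame(from = "N", to = "I", kex = 27.7))
#' buildRateMatrix(m)  # k_N->I ~ 0.3304, k_I->N ~ 27.37
#' @export
buildRateMatrix <- function(model) {
  stopifnot(is(model, "ExchangeModel"))
  validObject(model)
  st <- model@states
  S <- nrow(st)
  K <- matrix(0, S, S, dimnames = list(st$label, st$label))
  rt <- model@rates
  if (nrow(rt)) {
    for (e in seq_len(nrow(rt))) {
      i <- match(rt$from[e], st$label)
      j <- match(rt$to[e], st$label)
      psum <- st$population[i] + st$population[j]
      if (psum > 0) {
        K[j, i] <- K[j, i] + rt$kex[e] * st$population[j] / psum
        K[i, j] <- K[i, j] + rt$kex[e] * st$population[i] / psum
      }
    }
  }
  diag(K) <- -colSums(K)
  K
}
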