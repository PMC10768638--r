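#' Compile a unitary into a rectangular mesh of two-mode rotations
#'
#' Decomposes an `N x N` unitary into `N(N-1)/2` nearest-neighbour two-mode
#' layers `T(theta, phi) = rbind(c(exp(1i*phi)*cos(theta), -sin(theta)),
#' c(exp(1i*phi)*sin(theta), cos(theta)))` plus a final column of per-mode
#' output phases, following the rectangular (Clements-style) nulling scheme:
#' alternate diagonals are zeroed by right-multiplication with `T^-1` and
#' left-multiplication with `T`, and the residual left factors are commuted
#' through the diagonal so that the program reads
#' `U = diag(exp(1i * output_phases)) %*% T_1 %*% T_2 %*% ... %*% T_K`.
#'
#' @param U unitary matrix.
#' @param tol unitarity tolerance on the input.
#' @return object of class `interferometer_program`: list with `N`, `layers`
#'   (each a list with `mode` = lower mode index `m` of the pair `(m, m+1)`,
#'   `theta`, `phi`), and `output_phases` (length-`N` angles). Layers are in
#'   matrix-product order (leftmost factor first).
#' @seealso [clements_recompose()]
#' @export
clements_compile <- function(U, tol = 1e-10) {
  U <- as.matrix(U) + 0i
  N <- nrow(U)
  if (!is_unitary(U, tol)) {
    stop("clements_compile: input is not unitary within tolerance ", tol)
  }
  W <- U
  left <- list()   # ops applied as W <- T %*% W, in application order
  right <- list()  # ops applied as W <- W %*% T^-1, in application order
  if (N > 1L) {
    for (i in seq_len(N - 1L)) {
      if (i %% 2L == 1L) {
        for (j in 0:(i - 1L)) {
          rr <- N - j
          cc <- i - j
          # zero W[rr, cc] with a column op on (cc, cc+1)
          par <- null_params(W[rr, cc], W[rr, cc + 1L])
          W <- W %*% embed_T_inv(N, cc, par$theta, par$phi)
          right[[length(right) + 1L]] <- list(mode = cc, theta = par$theta,
                                              phi = par$phi)
        }
      } else {
        for (j in seq_len(i)) {
          rr <- N - i + j
          cc <- j
          # zero W[rr, cc] with a row op on (rr-1, rr)
          par <- null_params(-W[rr, cc], W[rr - 1L, cc])
          W <- embed_T(N, rr - 1L, par$theta, par$phi) %*% W
          left[[length(left) + 1L]] <- list(mode = rr - 1L, theta = par$theta,
                                            phi = par$phi)
        }
      }
    }
  }
  d <- diag(W)
  # U = left_1^-1 ... left_K^-1 D right_M ... right_1; push every left
  # inverse through the diagonal: T^-1(theta, phi) D = D' T(theta, phi').
  layers <- rev(right)
  for (j in rev(seq_along(left))) {
    op <- left[[j]]
    m <- op$mode
    d1 <- d[m]
    d2 <- d[m + 1L]
    if (abs(sin(op$theta)) < 1e-14) {
      phi2 <- 0
      d[m] <- exp(-1i * op$phi) * d1
    } else {
      phi2 <- Arg(-d1 / d2)
      d[m] <- -exp(-1i * op$phi) * d2
    }
    layers <- c(list(list(mode = m, theta = op$theta, phi = phi2)), layers)
  }
  structure(list(N = N, layers = layers, output_phases = Arg(d)),
            class = "interferometer_program")
}

# theta, phi with tan(theta) e^{i phi} = a / b, theta in [0, pi/2];
# zeroes e^{-i phi} cos(theta) * a - sin(theta) * b.
null_params <- function(a, b) {
  if (abs(b) < 1e-14 * max(abs(a), 1)) {
    if (abs(a) < 1e-14) return(list(theta = 0, phi = 0))
    return(list(theta = pi / 2, phi = 0))
  }
  ratio <- a / b
  list(theta = atan(Mod(ratio)), phi = Arg(ratio))
}

embed_T <- function(N, m, theta, phi) {
  M <- diag(1 + 0i, N)
  M[m, m] <- exp(1i * phi) * cos(theta)
  M[m, m + 1L] <- -sin(theta)
  M[m + 1L, m] <- exp(1i * phi) * sin(theta)
  M[m + 1L, m + 1L] <- cos(theta)
  M
}

embed_T_inv <- function(N, m, theta, phi) {
  Conj(t(embed_T(N, m, theta, phi)))
}

#' Recompose a unitary from an interferometer program
#'
#' @param prog object returned by [clements_compile()].
#' @return the `N x N` unitary `diag(exp(1i * output_phases)) %*% prod(T_l)`.
#' @export
clements_recompose <- function(prog) {
  stopifnot(inherits(prog, "interferometer_program"))
  N <- prog$N
  U <- diag(exp(1i * prog$output_phases), N)
  for (l in prog$layers) {
    U <- U %*% embed_T(N, l$mode, l$theta, l$phi)
  }
  U
}

#' @export
print.interferometer_program <- function(x, ...) {
  cat("Interferometer program on", x$N, "modes:",
      length(x$layers), "two-mode layers + output phases\n")
  invisible(x)
}
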