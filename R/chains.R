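# Chains: sparse formal sums of simplices with exact rational coefficients.
# A chain stores positions (`idx`) into the per-dimension simplex order of the
# filtration it belongs to, so identity of simplices is positional.

#' Construct a chain
#'
#' @param dim simplex dimension of the chain (1 for edge chains, 2 for
#'   triangle chains).
#' @param idx integer positions of the supporting simplices in the
#'   filtration's per-dimension order.
#' @param num,den exact rational coefficients as numerator/denominator pairs.
#' @return object of class `"chain"`.
#' @export
chain <- function(dim, idx = integer(0), num = numeric(0), den = rep(1, length(num))) {
  stopifnot(length(idx) == length(num), length(num) == length(den))
  r <- rat_simplify(num, den)
  keep <- r$num != 0
  o <- order(idx[keep])
  structure(list(dim = as.integer(dim),
                 idx = as.integer(idx[keep][o]),
                 num = r$num[keep][o],
                 den = r$den[keep][o]),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain> dimension %d, %d simplices (l1 = %g)\n",
              x$dim, length(x$idx), chain_l1(x)))
  invisible(x)
}

#' Support size (number of simplices with nonzero coefficient)
#' @param x a chain.
#' @export
chain_l0 <- function(x) length(x$idx)

#' Sum of absolute coefficient values
#' @param x a chain.
#' @export
chain_l1 <- function(x) sum(abs(x$num) / x$den)

chain_is_zero <- function(x) length(x$idx) == 0L

# a + c * b for chains over the same dimension/order; c given as num/den
chain_axpy <- function(a, b, cnum = 1, cden = 1) {
  stopifnot(a$dim == b$dim)
  idx <- union(a$idx, b$idx)
  num <- den <- numeric(length(idx))
  den[] <- 1
  ia <- match(a$idx, idx)
  num[ia] <- a$num; den[ia] <- a$den
  ib <- match(b$idx, idx)
  scaled <- rat_mul(b$num, b$den, rep(cnum, length(b$num)), rep(cden, length(b$num)))
  for (k in seq_along(ib)) {
    r <- rat_add(num[ib[k]], den[ib[k]], scaled$num[k], scaled$den[k])
    num[ib[k]] <- r$num; den[ib[k]] <- r$den
  }
  chain(a$dim, idx, num, den)
}

chain_negate <- function(a) chain(a$dim, a$idx, -a$num, a$den)

chain_equal <- function(a, b) {
  a$dim == b$dim && length(a$idx) == length(b$idx) &&
    all(a$idx == b$idx) && all(a$num == b$num) && all(a$den == b$den)
}

# dense double view on n slots (for solver interfaces and plotting)
chain_dense <- function(x, n) {
  v <- numeric(n)
  v[x$idx] <- x$num / x$den
  v
}
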