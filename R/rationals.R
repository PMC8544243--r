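# Small exact-rational toolkit used on the R side.  Heavy arithmetic lives in
# the C++ reduction; these helpers manipulate num/den pairs stored as doubles
# (exact for integers below 2^53, enforced).

.rat_check <- function(num, den) {
  if (any(den == 0)) stop("rational with zero denominator")
  if (any(abs(num) >= 2^53) || any(abs(den) >= 2^53))
    stop("rational arithmetic overflow (coefficient exceeds 53 bits)")
  invisible(NULL)
}

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- t
  }
  a
}

rat_simplify <- function(num, den) {
  .rat_check(num, den)
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- .gcd(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

rat_add <- function(n1, d1, n2, d2) rat_simplify(n1 * d2 + n2 * d1, d1 * d2)
rat_mul <- function(n1, d1, n2, d2) rat_simplify(n1 * n2, d1 * d2)
rat_div <- function(n1, d1, n2, d2) {
  if (any(n2 == 0)) stop("rational division by zero")
  rat_simplify(n1 * d2, d1 * n2)
}

#' Round floating-point values to nearby exact rationals
#'
#' Values within `tol` of an integer become that integer; anything else is
#' approximated by a continued-fraction convergent with denominator at most
#' `max_den`.  Used to lift solver output (doubles) back into the exact chain
#' arithmetic.
#'
#' @param x numeric vector.
#' @param tol absolute tolerance for snapping to integers.
#' @param max_den largest denominator considered.
#' @return list with components `num` and `den` (doubles holding integers).
#' @export
rat_approx <- function(x, tol = 1e-7, max_den = 1e6) {
  num <- den <- numeric(length(x))
  for (k in seq_along(x)) {
    v <- x[k]
    if (abs(v - round(v)) <= tol) {
      num[k] <- round(v); den[k] <- 1
      next
    }
    # continued fraction expansion
    h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- v
    repeat {
      a <- floor(b)
      h2 <- a * h1 + h0; k2 <- a * k1 + k0
      if (k2 > max_den) break
      h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
      if (abs(v - h1 / k1) < 1e-12) break
      if (b == a) break
      b <- 1 / (b - a)
    }
    num[k] <- h1; den[k] <- k1
  }
  rat_simplify(num, den)
}

# parse "p/q" or "p" strings into num/den
rat_parse <- function(s) {
  parts <- strsplit(as.character(s), "/", fixed = TRUE)
  num <- vapply(parts, function(p) as.numeric(p[1]), 0)
  den <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 1, 0)
  rat_simplify(num, den)
}

rat_format <- function(num, den) {
  ifelse(den == 1, sprintf("%d", as.integer(num)),
         sprintf("%d/%d", as.integer(num), as.integer(den)))
}
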