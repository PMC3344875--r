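# Independent oracles used across test files. These are deliberately written
# as plain-loop / closed-form implementations, separate from the package's
# vectorized code paths.

# eta-squared by direct evaluation of the defining sums
eta2_brute <- function(a, b) {
  num <- 0
  den <- 0
  M <- mean(c(a, b))
  for (i in seq_along(a)) {
    m_i <- (a[i] + b[i]) / 2
    num <- num + (a[i] - m_i)^2 + (b[i] - m_i)^2
    den <- den + (a[i] - M)^2 + (b[i] - M)^2
  }
  1 - num / den
}

# exhaustive per-pixel implementation of the Boundary/Background rules:
# direction by greatest 3-pixel linear sum (precedence h, v, down-right
# diagonal, up-right diagonal), candidate iff strictly greater than both
# on-mask orthogonal neighbors with the full triple present, Boundary iff in
# an 8-connected candidate component of size >= 3, Background iff no
# Boundary pixel among the 8 neighbors; isolated pixels are Neither
classify_brute <- function(values, mask = NULL) {
  h <- nrow(values); w <- ncol(values)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  orth_of <- c(2L, 1L, 4L, 3L)
  on <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j]
  val <- function(i, j) if (on(i, j)) values[i, j] else NA_real_
  cand <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    if (!mask[i, j]) next
    nn <- 0L
    for (a in -1:1) for (b in -1:1)
      if (!(a == 0 && b == 0) && on(i + a, j + b)) nn <- nn + 1L
    if (nn == 0L) next
    sums <- vapply(dirs, function(d) {
      s <- values[i, j]
      for (sgn in c(-1, 1)) {
        x <- val(i + sgn * d[1], j + sgn * d[2])
        if (!is.na(x)) s <- s + x
      }
      s
    }, numeric(1))
    o <- dirs[[orth_of[which.max(sums)]]]
    p1 <- val(i + o[1], j + o[2])
    p2 <- val(i - o[1], j - o[2])
    if (!is.na(p1) && !is.na(p2) && values[i, j] > p1 && values[i, j] > p2)
      cand[i, j] <- TRUE
  }
  lab <- matrix(0L, h, w); nl <- 0L
  for (i in 1:h) for (j in 1:w) {
    if (!cand[i, j] || lab[i, j] != 0L) next
    nl <- nl + 1L
    stack <- list(c(i, j)); lab[i, j] <- nl
    while (length(stack) > 0L) {
      p <- stack[[1]]; stack <- stack[-1]
      for (a in -1:1) for (b in -1:1) {
        x <- p[1] + a; y <- p[2] + b
        if (x >= 1 && x <= h && y >= 1 && y <= w && cand[x, y] &&
            lab[x, y] == 0L) {
          lab[x, y] <- nl
          stack <- c(stack, list(c(x, y)))
        }
      }
    }
  }
  sizes <- if (nl > 0L) tabulate(lab[lab > 0L], nl) else integer(0)
  boundary <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w)
    if (cand[i, j] && sizes[lab[i, j]] >= 3L) boundary[i, j] <- TRUE
  labels <- matrix(NA_character_, h, w)
  for (i in 1:h) for (j in 1:w) {
    if (!mask[i, j]) next
    nn <- 0L; bn <- FALSE
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      if (on(i + a, j + b)) {
        nn <- nn + 1L
        if (boundary[i + a, j + b]) bn <- TRUE
      }
    }
    labels[i, j] <- if (nn == 0L) "Neither"
      else if (boundary[i, j]) "Boundary"
      else if (!bn) "Background"
      else "Neither"
  }
  labels
}

# count of 8-connected components of a logical matrix (flood fill)
cc_count <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (s in which(bin)) {
    if (seen[s]) next
    n <- n + 1L
    stack <- s; seen[s] <- TRUE
    while (length(stack) > 0L) {
      p <- stack[1]; stack <- stack[-1]
      pr <- (p - 1L) %% h + 1L; pc <- (p - 1L) %/% h + 1L
      for (a in -1:1) for (b in -1:1) {
        x <- pr + a; y <- pc + b
        if (x >= 1 && x <= h && y >= 1 && y <= w) {
          q <- (y - 1L) * h + x
          if (bin[q] && !seen[q]) { seen[q] <- TRUE; stack <- c(stack, q) }
        }
      }
    }
  }
  n
}

# largest Chebyshev distance from any TRUE pixel of `found` to the TRUE set
# of `truth`
cheb_maxdist <- function(found, truth) {
  fd <- which(found, arr.ind = TRUE)
  tr <- which(truth, arr.ind = TRUE)
  if (nrow(fd) == 0L) return(NA_real_)
  max(vapply(seq_len(nrow(fd)), function(i)
    min(pmax(abs(tr[, 1] - fd[i, 1]), abs(tr[, 2] - fd[i, 2]))),
    numeric(1)))
}

# step map fixture: 0 on the left half, 1 from column `at` on
step_map <- function(h = 25, w = 25, at = 13) {
  v <- matrix(0, h, w)
  v[, at:w] <- 1
  scalar_map(v, matrix(TRUE, h, w), kind = "fisher_z", pixel_mm = 2)
}
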