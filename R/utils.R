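# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are deterministic
#' without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# signed dihedral (degrees, IUPAC convention) from four 3-vectors
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  # IUPAC sign: negative of the (m1.n2, n1.n2) atan2 form
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  # map to (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

# place a fourth atom given three anchors, bond length (A->new from p3),
# bond angle p2-p3-new (deg) and dihedral p1-p2-p3-new (deg); NeRF construction
place_atom <- function(p1, p2, p3, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(length * cos(pi - ang),
          length * sin(pi - ang) * cos(dih),
          length * sin(pi - ang) * sin(dih))
  bc <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  ab <- p2 - p1
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nv <- nv / sqrt(sum(nv^2))
  m2 <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  rot <- cbind(bc, m2, nv)
  as.vector(rot %*% d2) + p3
}

# Kabsch rotation + translation mapping moving (n x 3) onto fixed (n x 3);
# returns transformed full coordinate matrix 'apply_to' (m x 3)
kabsch_apply <- function(moving, fixed, apply_to) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm); b <- sweep(fixed, 2, cf)
  s <- svd(crossprod(a, b))
  dsign <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  sweep(sweep(apply_to, 2, cm) %*% t(r), 2, cf, "+")
}

# difference of two angles on the circle, result in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
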