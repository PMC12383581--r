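# Linear solvers for the FEM systems.
#
# SPD systems (steady/transient heat, Krylov preconditioner) go through
# CHOLMOD via Matrix::Cholesky.  The harmonic system K(1 + i eta) - w^2 M
# is complex symmetric (indefinite real part); large instances are solved
# with preconditioned Krylov iterations -- MINRES for the undamped real
# case, COCG (conjugate orthogonal CG) for the damped complex case --
# preconditioned with a CHOLMOD factorization of the SPD shift K + w^2 M.
# Small complex systems use a sparse LU of the equivalent 2n real block
# system.

chol_factor <- function(A) Matrix::Cholesky(Matrix::forceSymmetric(A),
                                            LDL = FALSE, super = TRUE)

chol_apply <- function(fac, b) {
  if (is.complex(b)) {
    z <- Matrix::solve(fac, cbind(Re(b), Im(b)), system = "A")
    z <- as.matrix(z)
    complex(real = z[, 1], imaginary = z[, 2])
  } else {
    as.numeric(Matrix::solve(fac, b, system = "A"))
  }
}

# preconditioned MINRES for real symmetric (possibly indefinite) A,
# SPD preconditioner given as a CHOLMOD factor
minres_solve <- function(Amul, b, pfac, tol = 1e-10, maxit = 2000) {
  n <- length(b)
  x <- numeric(n)
  r1 <- b
  y <- chol_apply(pfac, r1)
  beta1 <- sqrt(sum(r1 * y))
  if (!is.finite(beta1) || beta1 < 0)
    stop("preconditioner is not positive definite")
  if (beta1 == 0) return(list(x = x, iter = 0, relres = 0))
  # standard Paige-Saunders recurrence
  r2 <- r1
  beta <- beta1
  cs <- -1; sn <- 0
  phibar <- beta1
  w <- numeric(n); wl <- numeric(n); wl2 <- numeric(n)
  oldb <- 0; epsln <- 0; qrnorm <- beta1; dbar <- 0
  for (it in seq_len(maxit)) {
    v <- y / beta
    y <- Amul(v)
    if (it >= 2) y <- y - (beta / oldb) * r1
    alfa <- sum(v * y)
    y <- y - (alfa / beta) * r2
    r1 <- r2; r2 <- y
    y <- chol_apply(pfac, r2)
    oldb <- beta
    beta <- sqrt(sum(r2 * y))
    # QR update
    oldeps <- epsln
    delta <- cs * dbar + sn * alfa
    gbar <- sn * dbar - cs * alfa
    epsln <- sn * beta
    dbar <- -cs * beta
    gamma <- sqrt(gbar^2 + beta^2)
    gamma <- max(gamma, .Machine$double.eps)
    cs <- gbar / gamma
    sn <- beta / gamma
    phi <- cs * phibar
    phibar <- sn * phibar
    # update solution
    denom <- 1 / gamma
    wl2 <- wl; wl <- w
    w <- (v - oldeps * wl2 - delta * wl) * denom
    x <- x + phi * w
    qrnorm <- phibar
    if (qrnorm <= tol * beta1) break
  }
  list(x = x, iter = it, relres = qrnorm / beta1)
}

# COCG for complex symmetric A (unconjugated inner products), SPD real
# preconditioner applied through a CHOLMOD factor
cocg_solve <- function(Amul, b, pfac, tol = 1e-10, maxit = 2000) {
  n <- length(b)
  x <- complex(n)
  r <- b
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) return(list(x = x, iter = 0, relres = 0))
  z <- chol_apply(pfac, r)
  p <- z
  rho <- sum(r * z)
  for (it in seq_len(maxit)) {
    q <- Amul(p)
    denom <- sum(p * q)
    if (Mod(denom) == 0) stop("COCG breakdown (p' A p = 0); add damping")
    al <- rho / denom
    x <- x + al * p
    r <- r - al * q
    res <- sqrt(sum(Mod(r)^2)) / bnorm
    if (res <= tol) return(list(x = x, iter = it, relres = res))
    z <- chol_apply(pfac, r)
    rho_new <- sum(r * z)
    if (Mod(rho) == 0) stop("COCG breakdown (rho = 0); add damping")
    p <- z + (rho_new / rho) * p
    rho <- rho_new
  }
  list(x = x, iter = maxit, relres = res)
}

# direct solve of the complex system (Ar + i Ai) x = b via the 2n real
# block form; Ai may be a scalar multiple structure (Ai = ai_scale * Ai_mat)
complex_lu_solve <- function(Ar, Ai, b) {
  big <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  rhs <- c(Re(b), Im(b))
  z <- as.numeric(Matrix::solve(big, rhs))
  n <- length(b)
  complex(real = z[seq_len(n)], imaginary = z[n + seq_len(n)])
}
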