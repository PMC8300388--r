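#' VanRaden genomic relationship matrix
#'
#' `G = W W' / (2 * sum_k p_k (1 - p_k))` where `W = M - 2P` is the
#' column-centered dosage matrix and `p_k` is the frequency of the counted
#' allele at marker `k`, estimated from the dataset's own non-missing calls.
#' Missing dosages are mean-imputed to `2 p_k` (i.e. contribute 0 to `W`);
#' monomorphic markers contribute zero to both numerator and denominator.
#'
#' @param dataset a `genotype_dataset` (already restricted to the panel).
#' @return an object of class `grm`: the n x n relationship matrix with
#'   sample IDs as dimnames and attributes `denominator` and `p`.
#' @export
build_grm <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  D <- dataset$dosages
  storage.mode(D) <- "double"
  p <- colMeans(D, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  if (denom <= 0) stop("zero denominator: all markers monomorphic")
  W <- sweep(D, 2, 2 * p)
  W[is.na(W)] <- 0                                       # impute to 2 p_k
  W[, !poly] <- 0
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(dataset$samples, dataset$samples)
  structure(G, denominator = denom, p = p, class = c("grm", "matrix"))
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x), "x", ncol(x),
      sprintf("(mean diagonal %.3f, denominator %.4g)\n",
              mean(diag(x)), attr(x, "denominator")))
  invisible(x)
}

## Rotated-space helpers for the single-GRM mixed model
##   y = 1 mu + g + e,  Var(y) = G sg2 + I se2.
## With G = U diag(d) U', set yt = U'y, xt = U'1; every REML quantity is
## then O(n) per iteration. Pv applies the REML projection P to a rotated
## vector.
.reml_work <- function(y, G) {
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  list(d = d, yt = drop(crossprod(eg$vectors, y)),
       xt = drop(crossprod(eg$vectors, rep(1, length(y)))),
       U = eg$vectors, n = length(y))
}

.reml_quantities <- function(w, sg2, se2) {
  v <- sg2 * w$d + se2                                   # diag of rotated V
  xv <- sum(w$xt^2 / v)                                  # X'V^-1 X
  beta <- sum(w$xt * w$yt / v) / xv
  r <- (w$yt - w$xt * beta) / v                          # rotated P y
  Pvec <- function(z) z / v - (w$xt / v) * sum(w$xt * z / v) / xv
  ## tr(P A) for A diagonal (rotated): A = d (G) or 1 (I)
  trP <- function(a) sum(a / v) - sum(w$xt^2 * a / v^2) / xv
  logl <- -0.5 * (sum(log(v)) + log(xv) + sum(w$yt * r))
  list(v = v, beta = beta, r = r, Pvec = Pvec, trP = trP, logl = logl)
}

#' AI-REML variance components for GBLUP
#'
#' Estimates the additive genetic and residual variances of the model
#' `y = 1 mu + g + e`, `g ~ N(0, G sigma_g2)`, `e ~ N(0, I sigma_e2)` by
#' average-information REML. Newton steps use the average-information matrix
#' with step-halving on the restricted log-likelihood; a step that leaves the
#' parameter space, or an ill-conditioned AI system (e.g. `G = I`, where only
#' the total variance is identifiable), falls back to an EM-REML update.
#' Components are floored at `1e-8 * var(y)`. Convergence requires both the
#' relative parameter change and the log-likelihood change below `tol`.
#'
#' @param y numeric phenotype vector aligned to the GRM rows.
#' @param grm a [build_grm()] result (or any symmetric PSD matrix).
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance (default 1e-8).
#' @return a list of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `converged`, `n_iterations`, `log_likelihood`.
#' @export
ai_reml <- function(y, grm, max_iter = 100, tol = 1e-8) {
  n <- length(y)
  if (n != nrow(grm)) stop("y must align with the GRM")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= .Machine$double.eps) {
    ## zero-variance input: both components pinned at the floor
    return(structure(list(sigma_g2 = 1e-12, sigma_e2 = 1e-12,
                          converged = TRUE, n_iterations = 0L,
                          log_likelihood = NA_real_),
                     class = "variance_components"))
  }
  floor_v <- 1e-8 * vy
  w <- .reml_work(y, unclass(grm))
  sg2 <- se2 <- vy / 2
  q <- .reml_quantities(w, sg2, se2)
  conv <- FALSE; it <- 0
  logl_path <- q$logl

  for (it in seq_len(max_iter)) {
    ## score: dl/dtheta_i = -0.5 (tr(P A_i) - y'P A_i P y)
    PGy <- q$Pvec(w$d * q$r)
    PIy <- q$Pvec(q$r)
    yPGPy <- sum(w$d * q$r^2)
    yPIPy <- sum(q$r^2)
    score <- -0.5 * c(q$trP(w$d) - yPGPy, q$trP(rep(1, w$n)) - yPIPy)

    ## average information: 0.5 y'P A_i P A_j P y
    AI <- 0.5 * matrix(c(sum((w$d * q$r) * PGy), sum((w$d * q$r) * PIy),
                         sum(q$r * PGy), sum(q$r * PIy)), 2, 2)
    AI <- (AI + t(AI)) / 2

    em_step <- c(sg2 + sg2^2 * (yPGPy - q$trP(w$d)) / w$n,
                 se2 + se2^2 * (yPIPy - q$trP(rep(1, w$n))) / w$n)

    step_ok <- FALSE
    rc <- tryCatch(rcond(AI), error = function(e) 0)
    if (is.finite(rc) && rc > 1e-12) {
      delta <- solve(AI, score)
      halve <- 0
      while (halve <= 20) {
        cand <- c(sg2, se2) + delta / 2^halve
        if (all(cand > floor_v)) {
          qc <- .reml_quantities(w, cand[1], cand[2])
          if (qc$logl >= q$logl - 1e-12) {
            new <- cand; qnew <- qc; step_ok <- TRUE
            break
          }
        }
        halve <- halve + 1
      }
    }
    if (!step_ok) {                                      # EM-REML fallback
      new <- pmax(em_step, floor_v)
      qnew <- .reml_quantities(w, new[1], new[2])
    }

    ## parameter change scaled by the phenotypic variance so that a
    ## component pinned at the boundary can still converge
    rel <- max(abs(new - c(sg2, se2))) / vy
    dll <- abs(qnew$logl - q$logl)
    sg2 <- new[1]; se2 <- new[2]; q <- qnew
    logl_path <- c(logl_path, q$logl)
    if (rel < tol && dll < tol) { conv <- TRUE; break }
  }

  structure(list(sigma_g2 = sg2, sigma_e2 = se2, converged = conv,
                 n_iterations = it, log_likelihood = q$logl,
                 logl_path = logl_path),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  h2 <- x$sigma_g2 / (x$sigma_g2 + x$sigma_e2)
  cat(sprintf("variance_components: sigma_g2 %.6g, sigma_e2 %.6g (h2 %.3f), %s in %d iter\n",
              x$sigma_g2, x$sigma_e2, h2,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Solve the GBLUP mixed-model equations
#'
#' Joint solution of the overall mean and the genomic breeding values from
#' the single-trait mixed-model equations
#' `(Z'Z / sigma_e2 + (G sigma_g2)^-1) g_hat = Z'(y - mu_hat 1) / sigma_e2`,
#' with `mu_hat` from the generalized-least-squares mean equation solved
#' jointly. `Z` is the incidence of the training records onto the
#' individuals of the GRM; individuals without a record stay in `G` and
#' receive predictions through the same joint system.
#'
#' @param y_train named numeric vector of training phenotypes; names must
#'   match GRM row names. Alternatively unnamed with `train` supplying row
#'   indices.
#' @param grm_all GRM over all individuals (training and validation).
#' @param vc a [ai_reml()] result (or list with `sigma_g2`, `sigma_e2`).
#' @param train optional integer indices of the training rows in the GRM.
#' @return a list of class `mixed_model_fit`: `mu_hat`, `g_hat` (named,
#'   length n), `vc`, `train`.
#' @export
solve_mme <- function(y_train, grm_all, vc, train = NULL) {
  G <- unclass(grm_all)
  n <- nrow(G)
  if (is.null(train)) {
    if (is.null(names(y_train))) stop("y_train must be named or `train` given")
    train <- match(names(y_train), rownames(G))
    if (anyNA(train)) stop("training IDs absent from the GRM")
  }
  t_n <- length(train)
  stopifnot(length(y_train) == t_n)
  sg2 <- vc$sigma_g2; se2 <- vc$sigma_e2
  if (se2 <= 0) stop("sigma_e2 must be > 0")
  if (sg2 <= 1e-10 * se2) {
    ## full-shrinkage limit: the genetic effect carries no variance, so all
    ## GEBVs are 0 and the GLS mean reduces to the training mean
    g_hat <- stats::setNames(rep(0, n), rownames(G))
    return(structure(list(mu_hat = mean(y_train), g_hat = g_hat, vc = vc,
                          train = train),
                     class = "mixed_model_fit"))
  }

  Gs <- G * sg2
  rc <- tryCatch(rcond(Gs), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    warning("near-singular G: adding ridge 1e-8 * mean(diag) to its diagonal")
    Gs <- Gs + diag(1e-8 * mean(diag(Gs)), n)
  }
  Ginv <- solve(Gs)
  ## coefficient matrix over (mu, g_1..g_n)
  C <- matrix(0, n + 1, n + 1)
  C[1, 1] <- t_n / se2
  zrow <- numeric(n); zrow[train] <- 1 / se2
  C[1, -1] <- zrow; C[-1, 1] <- zrow
  C[-1, -1] <- Ginv
  diag(C)[1 + train] <- diag(C)[1 + train] + 1 / se2
  rhs <- c(sum(y_train) / se2,
           { r <- numeric(n); r[train] <- y_train / se2; r })
  sol <- solve(C, rhs)
  g_hat <- sol[-1]
  names(g_hat) <- rownames(G)
  structure(list(mu_hat = sol[1], g_hat = g_hat, vc = vc, train = train),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed_model_fit: mu_hat %.4g, %d GEBVs (%d training records)\n",
              x$mu_hat, length(x$g_hat), length(x$train)))
  invisible(x)
}
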