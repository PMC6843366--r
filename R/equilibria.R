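#' Host-guest binding model
#'
#' Defines the equilibrium system as a set of complex species `H_h G_g`
#' with log10 cumulative formation constants (the convention of global
#' titration-fitting programs).  The free species H (1,0) and G (0,1) are
#' implicitly present with `log beta = 0`.
#'
#' @param h,g integer host/guest counts per complex species (each `>= 0`,
#'   at least one species with `h >= 1` and `g >= 1`).
#' @param log_beta log10 cumulative formation constants, one per species.
#' @param absorbing which species contribute absorbance in a titration.
#'   Default: the free guest and every complex containing guest (the host
#'   is transparent in the UV for a cyclodextrin).  A logical vector over
#'   `c("H", "G", species...)` or character labels like `"G"`, `"H1G1"`.
#' @return An object of class `binding_model` with a species table holding
#'   the free species first.
#' @examples
#' binding_model(h = 1, g = 1, log_beta = log10(6025))
#' @export
binding_model <- function(h, g, log_beta, absorbing = NULL) {
  h <- as.integer(h); g <- as.integer(g)
  if (length(h) != length(g) || length(h) != length(log_beta))
    stop("h, g, log_beta must have equal length", call. = FALSE)
  if (any(h < 0) || any(g < 0) || any(h + g < 2L))
    stop("complex species need h >= 0, g >= 0, h + g >= 2", call. = FALSE)
  if (!any(h >= 1L & g >= 1L))
    stop("at least one mixed species (h >= 1, g >= 1) is required",
         call. = FALSE)
  key <- paste(h, g)
  if (anyDuplicated(key))
    stop("duplicate (h, g) species", call. = FALSE)
  species <- data.frame(
    label = c("H", "G", sprintf("H%dG%d", h, g)),
    h = c(1L, 0L, h), g = c(0L, 1L, g),
    log_beta = c(0, 0, as.numeric(log_beta)))
  if (is.null(absorbing)) {
    absorbing <- species$g >= 1L
  } else if (is.character(absorbing)) {
    if (!all(absorbing %in% species$label))
      stop("unknown absorbing species label", call. = FALSE)
    absorbing <- species$label %in% absorbing
  }
  species$absorbing <- absorbing
  structure(list(species = species), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("<binding_model>\n")
  print(x$species, row.names = FALSE)
  invisible(x)
}

# number of free (fitted) log_beta parameters
n_free_beta <- function(model) nrow(model$species) - 2L

#' Solve host-guest speciation by mass balance
#'
#' Solves the two mass-balance equations under mass action,
#' `[HhGg] = 10^logbeta [H]^h [G]^g`, for the free concentrations.  The
#' solver works in log-concentration space (positivity is automatic) with a
#' damped Newton iteration on the log-total residuals; zero totals are
#' handled as exact boundary cases.
#'
#' @param model a [binding_model()].
#' @param h_tot,g_tot total host and guest (M), `>= 0`.
#' @param tol relative convergence tolerance on both totals.
#' @param max_iter iteration cap.
#' @return An object of class `speciation`: `free_h`, `free_g`, and `conc`,
#'   a named vector over all model species (free species included).
#' @examples
#' m <- binding_model(1, 1, log10(6025))
#' solve_speciation(m, 4.43e-5, 4.43e-5)
#' @export
solve_speciation <- function(model, h_tot, g_tot, tol = 1e-12,
                             max_iter = 200L) {
  stopifnot(inherits(model, "binding_model"))
  if (h_tot < 0 || g_tot < 0) stop("totals must be >= 0", call. = FALSE)
  if (tol <= 0 || tol > 1e-6)
    stop("tol must be in (0, 1e-6]", call. = FALSE)
  sp <- model$species
  lb <- sp$log_beta * log(10)            # natural-log beta

  conc_of <- function(lnH, lnG) exp(lb + sp$h * lnH + sp$g * lnG)

  finish <- function(conc) {
    names(conc) <- sp$label
    structure(list(free_h = unname(conc["H"]), free_g = unname(conc["G"]),
                   conc = conc, h_tot = h_tot, g_tot = g_tot),
              class = "speciation")
  }

  if (h_tot == 0 && g_tot == 0) return(finish(numeric(nrow(sp))))
  if (h_tot == 0 || g_tot == 0) {
    # one-dimensional problem over the species of the surviving component
    tot <- max(h_tot, g_tot)
    count <- if (h_tot == 0) sp$g else sp$h
    other <- if (h_tot == 0) sp$h else sp$g
    live <- other == 0L & count >= 1L
    f <- function(lnx) log(sum(exp(lb[live] + count[live] * lnx))) - log(tot)
    lo <- log(tot) - 50; hi <- log(tot) + 1
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-15)$root
    conc <- numeric(nrow(sp))
    conc[live] <- exp(lb[live] + count[live] * root)
    return(finish(conc))
  }

  lnH <- log(h_tot); lnG <- log(g_tot)   # start at free = total
  converged <- 0L
  for (it in seq_len(max_iter)) {
    c_all <- conc_of(lnH, lnG)
    Ht <- sum(sp$h * c_all); Gt <- sum(sp$g * c_all)
    f1 <- log(Ht) - log(h_tot)
    f2 <- log(Gt) - log(g_tot)
    if (abs(f1) < tol && abs(f2) < tol) converged <- converged + 1L
    # polish with two extra Newton steps after first hitting tol: the
    # iteration is quadratic, so this lands at machine precision (bound
    # fractions near 0 or 1 amplify any slack in the free concentrations)
    if (converged > 2L || (abs(f1) < 1e-15 && abs(f2) < 1e-15)) {
      res <- max(abs(Ht - h_tot) / h_tot, abs(Gt - g_tot) / g_tot)
      if (res < tol * 10) return(finish(c_all))
    }
    # Jacobian of (log Ht, log Gt) wrt (lnH, lnG)
    j11 <- sum(sp$h^2 * c_all) / Ht
    j12 <- sum(sp$h * sp$g * c_all) / Ht
    j21 <- sum(sp$h * sp$g * c_all) / Gt
    j22 <- sum(sp$g^2 * c_all) / Gt
    det <- j11 * j22 - j12 * j21
    if (!is.finite(det) || abs(det) < 1e-300)
      stop("speciation Jacobian is singular", call. = FALSE)
    dH <- -(j22 * f1 - j12 * f2) / det
    dG <- -(-j21 * f1 + j11 * f2) / det
    step <- max(abs(dH), abs(dG))
    if (step > 5) { dH <- dH * 5 / step; dG <- dG * 5 / step }
    # damped: halve until the residual norm decreases
    norm0 <- abs(f1) + abs(f2)
    lam <- 1
    repeat {
      H2 <- lnH + lam * dH; G2 <- lnG + lam * dG
      c2 <- conc_of(H2, G2)
      n2 <- abs(log(sum(sp$h * c2)) - log(h_tot)) +
        abs(log(sum(sp$g * c2)) - log(g_tot))
      if (is.finite(n2) && (n2 < norm0 || lam < 1e-4)) break
      lam <- lam / 2
    }
    lnH <- lnH + lam * dH; lnG <- lnG + lam * dG
  }
  c_all <- conc_of(lnH, lnG)
  res <- max(abs(sum(sp$h * c_all) - h_tot) / h_tot,
             abs(sum(sp$g * c_all) - g_tot) / g_tot)
  if (res < tol * 10) return(finish(c_all))
  stop(sprintf("speciation did not converge (last relative residual %.3g)",
               res), call. = FALSE)
}

#' Titration dataset
#'
#' @param g_tot constant guest total (M), `> 0`.
#' @param h_tot host totals (M), one per titration point, non-negative and
#'   including 0 (the guest-only reference spectrum).
#' @param wavelengths nm grid.
#' @param absorbance matrix, `length(h_tot)` rows by `length(wavelengths)`
#'   columns.
#' @param path_length optical path (cm).
#' @return An object of class `titration_data`.
#' @export
titration_data <- function(g_tot, h_tot, wavelengths, absorbance,
                           path_length = 1) {
  absorbance <- as.matrix(absorbance)
  if (g_tot <= 0) stop("g_tot must be positive", call. = FALSE)
  if (any(h_tot < 0)) stop("h_tot must be non-negative", call. = FALSE)
  if (!any(h_tot == 0))
    stop("h_tot must include 0 (guest-only reference)", call. = FALSE)
  if (nrow(absorbance) != length(h_tot))
    stop("absorbance needs one row per titration point", call. = FALSE)
  if (ncol(absorbance) != length(wavelengths))
    stop("absorbance needs one column per wavelength", call. = FALSE)
  structure(list(g_tot = g_tot, h_tot = as.numeric(h_tot),
                 wavelengths = as.numeric(wavelengths),
                 absorbance = absorbance, path_length = path_length),
            class = "titration_data")
}

# speciation concentration matrix (points x absorbing species)
speciation_matrix <- function(model, data, tol = 1e-12) {
  abs_idx <- which(model$species$absorbing)
  C <- matrix(0, length(data$h_tot), length(abs_idx))
  for (i in seq_along(data$h_tot)) {
    st <- solve_speciation(model, data$h_tot[i], data$g_tot, tol = tol)
    C[i, ] <- st$conc[abs_idx]
  }
  colnames(C) <- model$species$label[abs_idx]
  C
}

#' Beer-Lambert forward model
#'
#' `A(point, lambda) = path * sum_s [s](point) * eps_s(lambda)` over the
#' absorbing species.
#'
#' @param model a [binding_model()].
#' @param epsilon matrix of molar absorptivities (M^-1 cm^-1), one row per
#'   absorbing species, one column per wavelength.
#' @param data a [titration_data()] (its absorbance slot may be a
#'   placeholder; only totals and path are used).
#' @return Predicted absorbance matrix (points x wavelengths).
#' @export
predict_absorbance <- function(model, epsilon, data) {
  epsilon <- as.matrix(epsilon)
  n_abs <- sum(model$species$absorbing)
  if (nrow(epsilon) != n_abs)
    stop("epsilon must have one row per absorbing species", call. = FALSE)
  C <- speciation_matrix(model, data)
  data$path_length * (C %*% epsilon)
}

# Exact small-p non-negative least squares, vectorized over right-hand
# sides sharing one design matrix: the NNLS optimum is the minimum-rss
# feasible unconstrained solution over all support subsets (its own
# support gives a feasible subset solution attaining the global minimum,
# and every subset solution is itself feasible), so for p <= ~4 subset
# enumeration is exact and each subset handles all columns at once.
nnls_columns <- function(X, Y) {
  p <- ncol(X)
  m <- ncol(Y)
  best_rss <- colSums(Y^2)                 # empty support
  best_B <- matrix(0, p, m)
  for (mask in seq_len(2^p - 1L)) {
    on <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    Xs <- X[, on, drop = FALSE]
    G <- tryCatch(solve(crossprod(Xs)), error = function(e) NULL)
    if (is.null(G)) next
    XtY <- crossprod(Xs, Y)
    B <- G %*% XtY
    rss <- colSums(Y^2) - colSums(B * XtY)
    ok <- colSums(B < 0) == 0L & rss < best_rss
    if (any(ok)) {
      best_rss[ok] <- rss[ok]
      best_B[, ok] <- 0
      best_B[on, ok] <- B[, ok]
    }
  }
  best_B
}

# inner varpro step: epsilon >= 0 per wavelength given the speciation C
project_epsilon <- function(C, A, path) {
  Xp <- path * C
  E <- tryCatch(qr.solve(crossprod(Xp), crossprod(Xp, A)),
                error = function(e) NULL)
  if (is.null(E)) E <- matrix(0, ncol(C), ncol(A))
  neg <- which(colSums(E < 0) > 0L)
  if (length(neg))
    E[, neg] <- nnls_columns(Xp, A[, neg, drop = FALSE])
  E[E < 0] <- 0
  E
}

titration_rss <- function(log_beta, model, data, tol = 1e-12) {
  model$species$log_beta[-(1:2)] <- log_beta
  C <- tryCatch(speciation_matrix(model, data, tol = tol),
                error = function(e) NULL)
  if (is.null(C)) return(list(rss = Inf))
  E <- project_epsilon(C, data$absorbance, data$path_length)
  R <- data$absorbance - data$path_length * (C %*% E)
  list(rss = sum(R^2), epsilon = E, residuals = R, C = C)
}

#' Global multiwavelength titration fit
#'
#' Fits cumulative formation constants to a full absorbance matrix by
#' variable projection: the outer problem is a bounded multistart
#' optimization over `log10 beta`; at each trial the speciation is solved
#' per titration point and the molar absorptivity spectra are obtained by
#' non-negative linear least squares per wavelength.  Standard errors come
#' from the curvature of the outer problem at the optimum.
#'
#' @param data a [titration_data()].
#' @param model a [binding_model()] giving the candidate stoichiometry
#'   (its `log_beta` values are used as one of the starts).
#' @param starts number of multistart points (`>= 5`) drawn from
#'   `log10 beta` in `[1, 6]`.
#' @param seed integer seed for the start draw.
#' @param alpha level for the residual-trend runs tests.
#' @return An object of class `titration_fit`: fitted `model`, `log_beta`,
#'   `log_beta_se`, `epsilon` (rows = absorbing species), `rss`, `aicc`,
#'   `residuals`, `trend` (see [residual_trend_test()]), `degenerate` flag.
#' @export
fit_titration <- function(data, model, starts = 7L, seed = 1L,
                          alpha = 0.05) {
  stopifnot(inherits(data, "titration_data"),
            inherits(model, "binding_model"))
  k <- n_free_beta(model)
  if (length(data$h_tot) < k + 2L)
    stop("need at least 2 more titration points than free constants",
         call. = FALSE)
  starts <- max(5L, as.integer(starts))
  if (max(abs(data$absorbance)) == 0) {
    return(structure(list(model = model, log_beta = rep(NA_real_, k),
                          log_beta_se = rep(NA_real_, k), epsilon = NULL,
                          rss = 0, aicc = NA_real_, residuals = NULL,
                          trend = NULL, degenerate = TRUE,
                          data = data),
                     class = "titration_fit"))
  }

  obj <- function(lb) titration_rss(lb, model, data)$rss
  start_mat <- rbind(model$species$log_beta[-(1:2)],
                     with_seed(seed, matrix(stats::runif((starts - 1L) * k,
                                                         1, 6),
                                            ncol = k)))
  best <- NULL
  for (i in seq_len(nrow(start_mat))) {
    fit <- try(stats::optim(start_mat[i, ], obj, method = "L-BFGS-B",
                            lower = rep(0, k), upper = rep(9, k),
                            control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all titration fit starts failed to converge", call. = FALSE)

  lb_hat <- best$par
  final <- titration_rss(lb_hat, model, data)
  n <- length(data$absorbance)
  n_eps <- length(final$epsilon)
  k_all <- k + n_eps + 1L
  aicc <- n * log(max(final$rss, 1e-300) / n) + 2 * k_all +
    if (n - k_all - 1L > 0) 2 * k_all * (k_all + 1L) / (n - k_all - 1L)
    else Inf

  # curvature-based SE for log_beta (outer problem)
  h <- 1e-4
  H <- matrix(NA_real_, k, k)
  f0 <- final$rss
  for (a in seq_len(k)) for (b in a:k) {
    ea <- eb <- rep(0, k); ea[a] <- h; eb[b] <- h
    if (a == b) {
      H[a, a] <- (obj(lb_hat + ea) - 2 * f0 + obj(lb_hat - ea)) / h^2
    } else {
      H[a, b] <- H[b, a] <- (obj(lb_hat + ea + eb) - obj(lb_hat + ea - eb) -
                               obj(lb_hat - ea + eb) +
                               obj(lb_hat - ea - eb)) / (4 * h^2)
    }
  }
  dof <- max(n - k_all, 1L)
  sigma2 <- final$rss / dof
  degenerate <- FALSE
  se <- rep(NA_real_, k)
  cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0) ||
      any(diag(H) < max(f0, 1e-12) * 1e-6)) {
    degenerate <- TRUE
  } else {
    se <- sqrt(diag(cov))
  }

  model$species$log_beta[-(1:2)] <- lb_hat
  out <- structure(list(model = model, log_beta = lb_hat, log_beta_se = se,
                        epsilon = final$epsilon, rss = final$rss,
                        aicc = aicc, residuals = final$residuals,
                        speciation = final$C, degenerate = degenerate,
                        data = data),
                   class = "titration_fit")
  out$trend <- residual_trend_test(out, alpha = alpha)
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  lab <- x$model$species$label[-(1:2)]
  cat("Global titration fit (variable projection)\n")
  for (i in seq_along(x$log_beta))
    cat(sprintf("  log10 beta(%s) = %.4f +/- %.4f   (K = %.4g)\n",
                lab[i], x$log_beta[i], x$log_beta_se[i], 10^x$log_beta[i]))
  cat(sprintf("  rss = %.4g, AICc = %.4g%s\n", x$rss, x$aicc,
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  if (!is.null(x$trend))
    cat(sprintf("  residual trend: %s (%.0f%% of wavelengths reject)\n",
                x$trend$verdict, 100 * x$trend$fraction_rejecting))
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) {
  stats::setNames(object$log_beta, object$model$species$label[-(1:2)])
}

#' @export
residuals.titration_fit <- function(object, ...) object$residuals

# one-sided Wald-Wolfowitz runs z-score: negative means too few runs
# (block-structured signs, i.e. a systematic trend)
runs_test_z <- function(signs) {
  n1 <- sum(signs > 0); n2 <- sum(signs <= 0)
  n <- n1 + n2
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  runs <- 1L + sum(diff(signs > 0) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  (runs - mu) / sqrt(v)
}

#' Residual-trend diagnosis for a titration fit
#'
#' Per wavelength, a one-sided Wald-Wolfowitz runs test on the residual
#' signs ordered by titration point (zero residuals count as positive);
#' too few runs mean block-structured residuals.  Two aggregations across
#' wavelengths are combined into the verdict: the fraction of wavelengths
#' rejecting randomness at `alpha` (systematic when it exceeds `alpha`
#' itself, i.e. more often than chance), and a Stouffer combination of the
#' per-wavelength runs z-scores (under the null the noise is independent
#' across wavelengths, so `sum(z)/sqrt(n)` is standard normal; a shared
#' misfit shape depresses every z a little even when no single wavelength
#' rejects on the handful of titration points available).  Either signal
#' declares the trend systematic.
#'
#' @param fit a [fit_titration()] result (or any object with a `residuals`
#'   matrix, points x wavelengths).
#' @param alpha test level.
#' @return List with `p_values` (per wavelength), `fraction_rejecting`,
#'   `combined_p` (Stouffer), `systematic` (logical) and `verdict`.
#' @export
residual_trend_test <- function(fit, alpha = 0.05) {
  R <- if (is.matrix(fit)) fit else fit$residuals
  if (is.null(R)) stop("no residual matrix present", call. = FALSE)
  signs <- sign(R)
  signs[signs == 0] <- 1                     # tie rule: zeros are positive
  z <- apply(signs, 2L, runs_test_z)
  p <- stats::pnorm(z)
  frac <- mean(p < alpha, na.rm = TRUE)
  if (!is.finite(frac)) frac <- 0
  z_ok <- z[is.finite(z)]
  combined_p <- if (length(z_ok))
    stats::pnorm(sum(z_ok) / sqrt(length(z_ok))) else NA_real_
  systematic <- frac > alpha ||
    (is.finite(combined_p) && combined_p < alpha)
  list(p_values = p, fraction_rejecting = frac, combined_p = combined_p,
       systematic = systematic,
       verdict = if (systematic) "systematic" else "no systematic trend")
}

#' Stoichiometry model selection
#'
#' Fits every candidate binding model to the same titration data and ranks
#' them: models whose residuals show no systematic trend come first, then
#' lower AICc (which charges richer models for their extra constants and
#' absorptivity spectra).
#'
#' @param data a [titration_data()].
#' @param candidates list of [binding_model()] objects (`>= 1`).
#' @param alpha runs-test level.
#' @param seed integer seed forwarded to each [fit_titration()].
#' @param starts multistart count per candidate.
#' @return An object of class `model_selection`: `table` (one row per
#'   candidate with rss, AICc, trend verdict, rank), `fits` (list),
#'   `best` (index of the selected model), `errors`.
#' @export
select_model <- function(data, candidates, alpha = 0.05, seed = 1L,
                         starts = 7L) {
  stopifnot(length(candidates) >= 1L)
  fits <- vector("list", length(candidates))
  errs <- character(length(candidates))
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(
      fit_titration(data, candidates[[i]], starts = starts,
                    seed = seed + i - 1L, alpha = alpha),
      error = function(e) { errs[i] <<- conditionMessage(e); NULL })
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("every candidate model failed to fit", call. = FALSE)
  tab <- data.frame(
    model = vapply(candidates, function(m)
      paste(sprintf("%d:%d", m$species$h[-(1:2)], m$species$g[-(1:2)]),
            collapse = "+"), ""),
    n_constants = vapply(candidates, n_free_beta, 1L),
    rss = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$rss, 1),
    aicc = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aicc, 1),
    systematic_trend = vapply(fits, function(f)
      if (is.null(f) || is.null(f$trend)) NA else f$trend$systematic, TRUE),
    error = errs)
  rank_key <- order(!ok, tab$systematic_trend, tab$aicc)
  tab$rank <- NA_integer_
  tab$rank[rank_key] <- seq_len(nrow(tab))
  structure(list(table = tab, fits = fits, best = rank_key[1L],
                 errors = errs[nzchar(errs)]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Stoichiometry model selection\n")
  print(x$table[order(x$table$rank),
                c("model", "n_constants", "rss", "aicc",
                  "systematic_trend", "rank")],
        row.names = FALSE, digits = 5)
  cat(sprintf("selected: %s\n", x$table$model[x$best]))
  invisible(x)
}
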