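#' Fit a multi-trait Bayesian mixed model by Gibbs sampling
#'
#' Runs a Markov chain whose stationary distribution is the posterior under:
#' Gaussian likelihoods for Gaussian traits; a Bernoulli-logit likelihood via
#' latent liabilities (residual liability variance fixed at 1) for binary
#' traits; a shared mother-level random effect vector per mother with
#' unstructured covariance `G` across traits; optional independent
#' individual-level effects for repeated-measures traits; residual
#' (co)variances free within each residual group and exactly zero across
#' groups; inverse-Wishart priors on each free covariance block; and
#' improper flat priors on fixed effects.
#'
#' Updates are blocked Gibbs steps (conjugate normal draws for fixed and
#' random effects, conditional inverse-Wishart draws for covariance blocks)
#' with a random-walk Metropolis step for binary-trait liabilities
#' ([update_binary_latents()]). Missing trait values within a multi-trait
#' residual unit are integrated out by drawing their latent residuals from
#' the conditional normal, which leaves the observed-data posterior exactly
#' equal to the model with those likelihood contributions omitted.
#'
#' @param table Observation table (long format, one row per
#'   trial/measurement; see [simulate_dataset()] / [read_observations()]).
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param quiet Suppress convergence warnings (effective sample size below
#'   200 for any (co)variance parameter).
#'
#' @return An object of class `mt_fit` with elements `samples` (matrix of
#'   retained draws, one named column per parameter), `iterations`, `spec`,
#'   `mcmc`, `ess` (for (co)variance parameters), and `accept_rate` for
#'   liability updates. Parameter names follow the convention
#'   `B.fixed[trait:term]`, `G.motherCov[traitA,traitB]`,
#'   `G.offspringVar[trait]`, `R.resid[traitA,traitB]`.
#' @seealso [decompose_variance()], [upper_limit_h2()], [tidy.mt_fit()]
#' @export
fit_model <- function(table, spec, mcmc = mcmc_config(), quiet = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  prep <- prepare_model_data(table, spec)
  fit <- with_seed(mcmc$seed, run_gibbs(prep, spec, mcmc))
  vc <- grepl("^(G\\.|R\\.)", colnames(fit$samples))
  ess <- vapply(which(vc), function(j) {
    x <- fit$samples[, j]
    if (sd(x) == 0) NA_real_ else suppressWarnings(effective_sample_size(x))
  }, numeric(1))
  names(ess) <- colnames(fit$samples)[vc]
  fit$ess <- ess
  low <- ess[!is.na(ess) & ess < 200]
  if (!quiet && length(low)) {
    warning(sprintf("low effective sample size (< 200) for: %s",
                    paste(names(low), collapse = ", ")), call. = FALSE)
  }
  fit
}

# ---- data preparation --------------------------------------------------

prepare_model_data <- function(table, spec) {
  tn <- names(spec$traits)
  table <- as.data.frame(table)
  if (!all(c("trait", "value", "individual_id", "mother_id") %in% names(table))) {
    stop("observation table must have trait, value, individual_id, mother_id columns",
         call. = FALSE)
  }
  if (!is.null(table$gps_east_m) && is.null(table$gps_east_km)) {
    table$gps_east_km <- table$gps_east_m / 1000
  }

  slices <- list()
  for (t in tn) {
    df <- table[table$trait == t, , drop = FALSE]
    if (!nrow(df)) stop(sprintf("trait '%s' is missing from the table", t), call. = FALSE)
    ts <- spec$traits[[t]]
    missing_cov <- setdiff(ts$fixed_effects, names(df))
    if (length(missing_cov)) {
      stop(sprintf("unknown covariate(s) for trait '%s': %s", t,
                   paste(missing_cov, collapse = ", ")), call. = FALSE)
    }
    if (ts$family == "binary_logit" && !all(df$value %in% c(0, 1))) {
      stop(sprintf("binary trait '%s' has values outside {0,1}", t), call. = FALSE)
    }
    for (cv in ts$fixed_effects) {
      if (any(is.na(df[[cv]]))) {
        stop(sprintf("covariate '%s' has missing values for trait '%s'", cv, t),
             call. = FALSE)
      }
      df[[cv]] <- as_model_term(df[[cv]], cv)
    }
    slices[[t]] <- df
  }

  tm <- mother_traits(spec)
  mother_levels <- character(0)
  for (t in tm) {
    mid <- slices[[t]]$mother_id
    if (any(is.na(mid))) {
      stop(sprintf("trait '%s' has rows without mother_id", t), call. = FALSE)
    }
    mother_levels <- union(mother_levels, mid)
  }
  mother_levels <- sort(mother_levels)

  groups <- lapply(spec$resid_groups, function(g) {
    build_group(g, slices, spec, mother_levels)
  })

  v_levels <- list()
  for (t in individual_traits(spec)) {
    v_levels[[t]] <- sort(unique(slices[[t]]$individual_id))
  }

  list(slices = slices, groups = groups, mother_levels = mother_levels,
       v_levels = v_levels, trait_names = tn, mother_traits = tm)
}

as_model_term <- function(x, name) {
  if (is.numeric(x) && !name %in% c("year", "cohort")) return(x)
  x <- as.character(x)
  lev <- sort(unique(x))
  base <- switch(name,
                 sex = if ("male" %in% lev) "male" else lev[1],
                 year = if ("2017" %in% lev) "2017" else lev[1],
                 cohort = lev[1],
                 companion_class = if ("alone" %in% lev) "alone" else lev[1],
                 observer_id = lev[1],
                 lev[1])
  factor(x, levels = c(base, setdiff(lev, base)))
}

build_group <- function(g, slices, spec, mother_levels) {
  Tg <- length(g)
  has_mother <- vapply(g, function(t) "mother" %in% spec$traits[[t]]$random, logical(1))
  binary <- vapply(g, function(t) spec$traits[[t]]$family == "binary_logit", logical(1))
  fixed_resid <- vapply(g, function(t) spec$traits[[t]]$resid_fixed %||% NA_real_, numeric(1))

  if (sum(binary) > 1L) {
    stop("at most one binary trait per residual group is supported", call. = FALSE)
  }

  if (Tg == 1L) {
    df <- slices[[g]]
    n <- nrow(df)
    X <- design_matrix(df, spec$traits[[g]])
    Y <- matrix(if (binary) ifelse(df$value == 1, 0.5, -0.5) else df$value, ncol = 1)
    obs <- matrix(TRUE, n, 1)
    O <- matrix(if (binary) df$value else NA_real_, ncol = 1)
    mother <- if (has_mother) match(df$mother_id, mother_levels) else rep(NA_integer_, n)
    v_index <- if ("individual" %in% spec$traits[[g]]$random) {
      match(df$individual_id, sort(unique(df$individual_id)))
    } else NULL
    unit_id <- df$observation_id %||% as.character(seq_len(n))
  } else {
    unit_id <- sort(unique(unlist(lapply(g, function(t) slices[[t]]$individual_id))))
    n <- length(unit_id)
    Y <- matrix(NA_real_, n, Tg)
    obs <- matrix(FALSE, n, Tg)
    O <- matrix(NA_real_, n, Tg)
    X <- vector("list", Tg)
    mother <- rep(NA_integer_, n)
    for (j in seq_len(Tg)) {
      df <- slices[[g[j]]]
      if (anyDuplicated(df$individual_id)) {
        stop(sprintf("multi-trait residual group needs one row per individual for trait '%s' (average repeated measures first)",
                     g[j]), call. = FALSE)
      }
      u_idx <- match(df$individual_id, unit_id)
      Xobs <- design_matrix(df, spec$traits[[g[j]]])
      Xfull <- matrix(0, n, ncol(Xobs), dimnames = list(NULL, colnames(Xobs)))
      if ("(Intercept)" %in% colnames(Xfull)) Xfull[, "(Intercept)"] <- 1
      Xfull[u_idx, ] <- Xobs
      X[[j]] <- Xfull
      Y[u_idx, j] <- if (binary[j]) ifelse(df$value == 1, 0.5, -0.5) else df$value
      obs[u_idx, j] <- TRUE
      if (binary[j]) O[u_idx, j] <- df$value
      mj <- match(df$mother_id, mother_levels)
      clash <- !is.na(mother[u_idx]) & mother[u_idx] != mj
      if (any(clash)) {
        stop("an individual maps to different mothers across traits", call. = FALSE)
      }
      mother[u_idx] <- mj
    }
    Y[!obs] <- 0
    X <- stats::setNames(X, g)
    v_index <- NULL
  }
  if (Tg == 1L) X <- stats::setNames(list(X), g)

  XtX <- vector("list", Tg * Tg)
  dim(XtX) <- c(Tg, Tg)
  for (i in seq_len(Tg)) for (j in seq_len(Tg)) {
    XtX[[i, j]] <- crossprod(X[[i]], X[[j]])
  }

  # static missingness patterns for the augmentation step
  miss_patterns <- list()
  if (any(!obs)) {
    pat <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
    for (p in unique(pat[rowSums(obs) < Tg])) {
      rows <- which(pat == p)
      ob <- obs[rows[1], ]
      miss_patterns[[length(miss_patterns) + 1L]] <-
        list(rows = rows, mis = which(!ob), obs = which(ob))
    }
  }

  list(traits = g, Tg = Tg, n = n, unit_id = unit_id, Y = Y, obs = obs, O = O,
       X = X, XtX = XtX, mother = mother, has_mother = has_mother,
       agg_m = if (any(has_mother)) make_agg(mother, length(mother_levels)) else NULL,
       agg_v = if (!is.null(v_index)) make_agg(v_index, max(v_index)) else NULL,
       binary = binary, fixed_resid = fixed_resid, v_index = v_index,
       miss_patterns = miss_patterns)
}

# Precompute an order/run-ends structure so per-iteration group sums are a
# cumsum + diff instead of rowsum()'s repeated unique/ordering work.
make_agg <- function(index, n_levels) {
  ord <- order(index)
  sorted <- index[ord]
  r <- rle(sorted)
  list(ord = ord, ends = cumsum(r$lengths), ids = r$values, n_levels = n_levels)
}

agg_sum <- function(x, agg) {
  s <- cumsum(x[agg$ord])
  out <- numeric(agg$n_levels)
  out[agg$ids] <- diff(c(0, s[agg$ends]))
  out
}

design_matrix <- function(df, ts) {
  if (!length(ts$fixed_effects)) {
    X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  df <- droplevels(df)
  X <- model.matrix(stats::reformulate(ts$fixed_effects), data = df)
  if (qr(X)$rank < ncol(X)) {
    stop(sprintf("design matrix for trait '%s' is rank-deficient", ts$name), call. = FALSE)
  }
  X
}

# ---- the sampler -------------------------------------------------------

run_gibbs <- function(prep, spec, mcmc) {
  groups <- prep$groups
  tn <- prep$trait_names
  tm <- prep$mother_traits
  pG <- length(tm)
  n_mothers <- length(prep$mother_levels)
  prior <- spec$prior

  # state ----------------------------------------------------------------
  beta <- lapply(groups, function(gr) {
    lapply(seq_len(gr$Tg), function(j) {
      b <- rep(0, ncol(gr$X[[j]]))
      names(b) <- colnames(gr$X[[j]])
      if ("(Intercept)" %in% names(b)) {
        b[["(Intercept)"]] <- mean(gr$Y[gr$obs[, j], j])
      }
      b
    })
  })
  U <- matrix(0, n_mothers, pG, dimnames = list(prep$mother_levels, tm))
  v <- lapply(prep$v_levels, function(lv) stats::setNames(rep(0, length(lv)), lv))
  sigma_v <- stats::setNames(rep(1, length(v)), names(v))

  G <- if (pG > 0) {
    init <- vapply(tm, function(t) {
      y <- trait_values(groups, t)
      max(stats::var(y) / 4, 0.05)
    }, numeric(1))
    diag(init, pG)
  } else NULL
  if (!is.null(G)) dimnames(G) <- list(tm, tm)

  Rg <- lapply(groups, function(gr) {
    vr <- vapply(seq_len(gr$Tg), function(j) {
      if (!is.na(gr$fixed_resid[j])) return(gr$fixed_resid[j])
      max(stats::var(gr$Y[gr$obs[, j], j]) / 2, 0.05)
    }, numeric(1))
    diag(vr, gr$Tg)
  })
  Sdelta <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    if (gr$Tg > 1L && any(gr$binary)) {
      Sdelta[[k]] <- diag(diag(Rg[[k]])[!gr$binary], sum(!gr$binary))
    }
  }

  prop_sd <- lapply(groups, function(gr) {
    if (any(gr$binary)) rep(mcmc$proposal_sd, gr$n) else NULL
  })
  acc_count <- 0; acc_n <- 0

  # retained-sample bookkeeping -------------------------------------------
  keep_iters <- seq(mcmc$burn_in + mcmc$thin, mcmc$n_iter, by = mcmc$thin)
  par_names <- sample_names(spec, groups, beta, tm, names(v))
  S <- matrix(NA_real_, length(keep_iters), length(par_names),
              dimnames = list(NULL, par_names))
  k_out <- 0L

  # cached fixed-effect predictors X %*% beta per group (refreshed in (b))
  Xb <- lapply(seq_along(groups), function(k) {
    gr <- groups[[k]]
    m <- matrix(0, gr$n, gr$Tg)
    for (j in seq_len(gr$Tg)) m[, j] <- drop(gr$X[[j]] %*% beta[[k]][[j]])
    m
  })

  eta_group <- function(gr, k) {
    Eta <- Xb[[k]]
    for (j in seq_len(gr$Tg)) {
      t_name <- gr$traits[j]
      if (gr$has_mother[j]) {
        Eta[, j] <- Eta[, j] + U[gr$mother, t_name]
      }
      if (!is.null(gr$v_index) && t_name %in% names(v)) {
        Eta[, j] <- Eta[, j] + v[[t_name]][gr$v_index]
      }
    }
    Eta
  }

  # static design quantities for the mother-effect update
  m_counts <- matrix(0L, n_mothers, length(groups))
  m_sel <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    if (!any(gr$has_mother)) next
    sel <- match(gr$traits, tm)
    keep <- which(!is.na(sel) & gr$has_mother)
    m_sel[[k]] <- list(sel = sel, keep = keep)
    m_counts[, k] <- tabulate(gr$mother, nbins = n_mothers)
  }
  if (pG > 2) {
    m_key <- apply(m_counts, 1, paste, collapse = ",")
    m_patterns <- lapply(unique(m_key), function(p) which(m_key == p))
  }

  for (iter in seq_len(mcmc$n_iter)) {
    # (a) latent liabilities and augmented residuals -----------------------
    for (k in seq_along(groups)) {
      gr <- groups[[k]]
      if (!any(gr$binary) && !length(gr$miss_patterns)) next
      R <- Rg[[k]]
      Eta <- eta_group(gr, k)
      Y <- gr$Y
      # augmented (unobserved) cells: conditional normal given observed cells
      if (length(gr$miss_patterns)) {
        for (mp in gr$miss_patterns) {
          rows <- mp$rows
          mis <- mp$mis; obs_ix <- mp$obs
          if (!length(obs_ix)) {
            cc <- chol_psd(R[mis, mis, drop = FALSE])
            Y[rows, mis] <- Eta[rows, mis, drop = FALSE] +
              matrix(rnorm(length(rows) * length(mis)), length(rows)) %*% cc
            next
          }
          B <- R[mis, obs_ix, drop = FALSE] %*%
            chol2inv(chol(R[obs_ix, obs_ix, drop = FALSE]))
          cc <- R[mis, mis, drop = FALSE] - B %*% R[obs_ix, mis, drop = FALSE]
          Eres <- Y[rows, obs_ix, drop = FALSE] - Eta[rows, obs_ix, drop = FALSE]
          mu <- Eta[rows, mis, drop = FALSE] + Eres %*% t(B)
          Y[rows, mis] <- mu + matrix(rnorm(length(rows) * length(mis)),
                                      length(rows)) %*% chol_psd(cc)
        }
      }
      # observed binary cells: Metropolis on the liability
      if (any(gr$binary)) {
        j <- which(gr$binary)
        rows <- which(gr$obs[, j])
        if (gr$Tg == 1L) {
          pred <- Eta[rows, 1]
          csd <- sqrt(R[1, 1])
        } else {
          oth <- setdiff(seq_len(gr$Tg), j)
          Bc <- R[j, oth, drop = FALSE] %*% chol2inv(chol(R[oth, oth, drop = FALSE]))
          cvar <- drop(R[j, j] - Bc %*% R[oth, j, drop = FALSE])
          shift <- (Y[rows, oth, drop = FALSE] - Eta[rows, oth, drop = FALSE]) %*% t(Bc)
          pred <- Eta[rows, j] + drop(shift)
          csd <- sqrt(max(cvar, 1e-10))
        }
        l_new <- update_binary_latents(Y[rows, j], pred, gr$O[rows, j],
                                       tuning = prop_sd[[k]][rows], resid_sd = csd)
        acc <- attr(l_new, "accepted")
        Y[rows, j] <- as.numeric(l_new)
        acc_count <- acc_count + sum(acc); acc_n <- acc_n + length(acc)
        if (mcmc$adapt && iter <= mcmc$burn_in) {
          prop_sd[[k]][rows] <- pmin(pmax(
            prop_sd[[k]][rows] * exp(0.05 * (as.numeric(acc) - 0.44)), 0.1), 20)
        }
      }
      groups[[k]]$Y <- Y
    }

    # (b) fixed effects per residual group ---------------------------------
    for (k in seq_along(groups)) {
      gr <- groups[[k]]
      Rinv <- chol2inv(chol(Rg[[k]]))
      # residual without fixed effects: Y - (U + v) contributions
      D <- gr$Y
      for (j in seq_len(gr$Tg)) {
        t_name <- gr$traits[j]
        if (gr$has_mother[j]) {
          D[, j] <- D[, j] - U[gr$mother, t_name]
        }
        if (!is.null(gr$v_index) && t_name %in% names(v)) {
          D[, j] <- D[, j] - v[[t_name]][gr$v_index]
        }
      }
      p_t <- vapply(seq_len(gr$Tg), function(j) ncol(gr$X[[j]]), integer(1))
      off <- c(0L, cumsum(p_t))
      P <- matrix(0, sum(p_t), sum(p_t))
      b <- numeric(sum(p_t))
      for (i in seq_len(gr$Tg)) {
        ri <- (off[i] + 1L):off[i + 1L]
        for (j in seq_len(gr$Tg)) {
          rj <- (off[j] + 1L):off[j + 1L]
          P[ri, rj] <- P[ri, rj] + Rinv[i, j] * gr$XtX[[i, j]]
          b[ri] <- b[ri] + Rinv[i, j] * drop(crossprod(gr$X[[i]], D[, j]))
        }
      }
      Uc <- chol(P)
      mean_b <- backsolve(Uc, forwardsolve(t(Uc), b))
      draw <- mean_b + backsolve(Uc, rnorm(length(b)))
      for (j in seq_len(gr$Tg)) {
        beta[[k]][[j]][] <- draw[(off[j] + 1L):off[j + 1L]]
        Xb[[k]][, j] <- drop(gr$X[[j]] %*% beta[[k]][[j]])
      }
    }

    # (c) mother-level effect vectors --------------------------------------
    if (pG > 0) {
      Ginv <- chol2inv(chol(G))
      Bm <- matrix(0, n_mothers, pG)
      A_list <- vector("list", length(groups))
      for (k in seq_along(groups)) {
        gr <- groups[[k]]
        if (is.null(m_sel[[k]])) next
        Rinv <- chol2inv(chol(Rg[[k]]))
        sel <- m_sel[[k]]$sel; keep <- m_sel[[k]]$keep
        A <- matrix(0, pG, pG)
        A[sel[keep], sel[keep]] <- Rinv[keep, keep]
        A_list[[k]] <- A
        # residual without mother effects
        E0 <- gr$Y - Xb[[k]]
        for (j in seq_len(gr$Tg)) {
          t_name <- gr$traits[j]
          if (!is.null(gr$v_index) && t_name %in% names(v)) {
            E0[, j] <- E0[, j] - v[[t_name]][gr$v_index]
          }
        }
        W <- if (gr$Tg == 1L) E0 * Rinv[1, 1] else E0 %*% Rinv
        for (jj in seq_along(keep)) {
          cc <- sel[keep[jj]]
          Bm[, cc] <- Bm[, cc] + agg_sum(W[, keep[jj]], gr$agg_m)
        }
      }
      if (pG == 1L) {
        prec <- drop(Ginv) +
          drop(m_counts %*% vapply(seq_along(groups), function(k)
            if (is.null(A_list[[k]])) 0 else A_list[[k]][1, 1], numeric(1)))
        U[, 1] <- Bm[, 1] / prec + rnorm(n_mothers) / sqrt(prec)
      } else if (pG == 2L) {
        a11 <- rep(Ginv[1, 1], n_mothers)
        a12 <- rep(Ginv[1, 2], n_mothers)
        a22 <- rep(Ginv[2, 2], n_mothers)
        for (k in seq_along(groups)) {
          A <- A_list[[k]]
          if (is.null(A)) next
          ck <- m_counts[, k]
          a11 <- a11 + ck * A[1, 1]
          a12 <- a12 + ck * A[1, 2]
          a22 <- a22 + ck * A[2, 2]
        }
        # elementwise lower Cholesky of each 2x2 precision, solve and draw
        l11 <- sqrt(a11)
        l21 <- a12 / l11
        l22 <- sqrt(a22 - l21^2)
        # mean: solve P mu = b via L L'
        w1 <- Bm[, 1] / l11
        w2 <- (Bm[, 2] - l21 * w1) / l22
        mu2 <- w2 / l22
        mu1 <- (w1 - l21 * mu2) / l11
        z1 <- rnorm(n_mothers); z2 <- rnorm(n_mothers)
        d2 <- z2 / l22
        d1 <- (z1 - l21 * d2) / l11
        U[, 1] <- mu1 + d1
        U[, 2] <- mu2 + d2
      } else {
        for (mrows in m_patterns) {
          Pm <- Ginv
          for (k in seq_along(groups)) {
            if (!is.null(A_list[[k]]) && m_counts[mrows[1], k] > 0) {
              Pm <- Pm + m_counts[mrows[1], k] * A_list[[k]]
            }
          }
          Uc <- chol(Pm)
          rhs <- t(Bm[mrows, , drop = FALSE])
          mu <- backsolve(Uc, forwardsolve(t(Uc), rhs))
          z <- matrix(rnorm(pG * length(mrows)), pG)
          U[mrows, ] <- t(mu + backsolve(Uc, z))
        }
      }
    }

    # (d) individual-level effects ------------------------------------------
    for (t_name in names(v)) {
      k <- which(vapply(groups, function(gr) t_name %in% gr$traits && gr$Tg == 1L,
                        logical(1)))[1]
      gr <- groups[[k]]
      r <- Rg[[k]][1, 1]
      d <- gr$Y[, 1] - Xb[[k]][, 1]
      if (gr$has_mother[1]) {
        d <- d - U[gr$mother, t_name]
      }
      kc <- tabulate(gr$v_index, nbins = length(v[[t_name]]))
      sums <- agg_sum(d, gr$agg_v)
      prec <- 1 / sigma_v[[t_name]] + kc / r
      v[[t_name]][] <- (sums / r) / prec + rnorm(length(kc)) / sqrt(prec)
    }

    # (e) mother covariance matrix ------------------------------------------
    if (pG > 0) {
      VG <- if (is.matrix(prior$G$V)) prior$G$V else diag(prior$G$V, pG)
      G <- rinvwishart(VG + crossprod(U), prior$G$nu + n_mothers)
      dimnames(G) <- list(tm, tm)
    }

    # (f) individual-level variances ----------------------------------------
    for (t_name in names(v)) {
      sigma_v[[t_name]] <- drop(rinvwishart(
        matrix(prior$v$V + sum(v[[t_name]]^2)), prior$v$nu + length(v[[t_name]])))
    }

    # (g) residual covariances ----------------------------------------------
    for (k in seq_along(groups)) {
      gr <- groups[[k]]
      E <- gr$Y - eta_group(gr, k)
      pr <- prior$R[[k]]
      if (gr$Tg == 1L) {
        if (!is.na(gr$fixed_resid[1])) next
        Rg[[k]] <- rinvwishart(matrix(pr$V[1, 1] + sum(E[, 1]^2)), pr$nu + gr$n)
      } else if (!any(gr$binary)) {
        Rg[[k]] <- rinvwishart(pr$V + crossprod(E), pr$nu + gr$n)
      } else {
        j <- which(gr$binary)
        gix <- which(!gr$binary)
        eb <- E[, j]
        Eg <- E[, gix, drop = FALSE]
        sb2 <- sum(eb^2)
        bhat <- drop(crossprod(Eg, eb)) / sb2
        Ld <- chol_psd(Sdelta[[k]])
        bdraw <- bhat + drop(rnorm(length(gix)) %*% Ld) / sqrt(sb2)
        delta <- Eg - outer(eb, bdraw)
        q <- length(gix)
        Sdelta[[k]] <- rinvwishart(diag(q) + crossprod(delta), q + 0.002 + gr$n)
        R <- matrix(0, gr$Tg, gr$Tg)
        R[gix, gix] <- Sdelta[[k]] + outer(bdraw, bdraw)
        R[gix, j] <- bdraw
        R[j, gix] <- bdraw
        R[j, j] <- 1
        Rg[[k]] <- R
      }
    }

    # record ----------------------------------------------------------------
    if (iter > mcmc$burn_in && (iter - mcmc$burn_in) %% mcmc$thin == 0L) {
      k_out <- k_out + 1L
      S[k_out, ] <- collect_sample(spec, groups, beta, U, v, sigma_v, G, Rg, tm)
    }
  }

  structure(list(
    samples = S,
    iterations = keep_iters,
    spec = spec,
    mcmc = mcmc,
    trait_names = tn,
    mother_traits = tm,
    n_mothers = n_mothers,
    mother_levels = prep$mother_levels,
    accept_rate = if (acc_n > 0) acc_count / acc_n else NA_real_
  ), class = "mt_fit")
}

trait_values <- function(groups, t_name) {
  for (gr in groups) {
    j <- match(t_name, gr$traits)
    if (!is.na(j)) return(gr$Y[gr$obs[, j], j])
  }
  numeric(0)
}

sample_names <- function(spec, groups, beta, tm, v_names) {
  tn <- names(spec$traits)
  nm <- character(0)
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    for (j in seq_len(gr$Tg)) {
      nm <- c(nm, sprintf("B.fixed[%s:%s]", gr$traits[j], names(beta[[k]][[j]])))
    }
  }
  if (length(tm)) {
    for (i in seq_along(tm)) for (j in i:length(tm)) {
      nm <- c(nm, sprintf("G.motherCov[%s,%s]", tm[i], tm[j]))
    }
  }
  nm <- c(nm, sprintf("G.offspringVar[%s]", v_names))
  for (i in seq_along(tn)) for (j in i:length(tn)) {
    nm <- c(nm, sprintf("R.resid[%s,%s]", tn[i], tn[j]))
  }
  nm
}

collect_sample <- function(spec, groups, beta, U, v, sigma_v, G, Rg, tm) {
  tn <- names(spec$traits)
  out <- numeric(0)
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    for (j in seq_len(gr$Tg)) out <- c(out, beta[[k]][[j]])
  }
  if (length(tm)) {
    for (i in seq_along(tm)) for (j in i:length(tm)) {
      out <- c(out, G[tm[i], tm[j]])
    }
  }
  out <- c(out, unlist(sigma_v, use.names = FALSE))
  # residual matrix over all traits, cross-group elements exactly zero
  Rfull <- matrix(0, length(tn), length(tn), dimnames = list(tn, tn))
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    Rfull[gr$traits, gr$traits] <- Rg[[k]]
  }
  for (i in seq_along(tn)) for (j in i:length(tn)) {
    out <- c(out, Rfull[i, j])
  }
  out
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf("Multi-trait mixed model fit: %d retained samples, %d parameters\n",
              nrow(x$samples), ncol(x$samples)))
  cat(sprintf("  traits: %s\n", paste(x$trait_names, collapse = ", ")))
  cat(sprintf("  mothers: %d; MCMC %d iterations (burn-in %d, thin %d), seed %d\n",
              x$n_mothers, x$mcmc$n_iter, x$mcmc$burn_in, x$mcmc$thin, x$mcmc$seed))
  if (!is.na(x$accept_rate)) {
    cat(sprintf("  liability Metropolis acceptance: %.2f\n", x$accept_rate))
  }
  invisible(x)
}

#' Tidy posterior draws from a fitted multi-trait model
#'
#' @param x An `mt_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `parameter_name`, `value`
#'   (the long serialisation used by [write_posterior()]).
#' @export
tidy.mt_fit <- function(x, ...) {
  tibble::tibble(
    iteration = rep(x$iterations, times = ncol(x$samples)),
    parameter_name = rep(colnames(x$samples), each = nrow(x$samples)),
    value = as.numeric(x$samples)
  )
}

#' @rdname tidy.mt_fit
#' @return For `glance()`: a one-row tibble with the retained sample count,
#'   parameter count, minimum (co)variance-parameter ESS and liability
#'   acceptance rate.
#' @export
glance.mt_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_parameters = ncol(x$samples),
    min_ess = if (length(x$ess)) min(x$ess, na.rm = TRUE) else NA_real_,
    accept_rate = x$accept_rate
  )
}

# Accept an mt_fit, a wide samples matrix, or a long tidy tibble.
as_sample_matrix <- function(x) {
  if (inherits(x, "mt_fit")) return(x$samples)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && all(c("iteration", "parameter_name", "value") %in% names(x))) {
    wide <- tidyr::pivot_wider(x, id_cols = "iteration",
                               names_from = "parameter_name", values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- NULL
    return(m)
  }
  stop("cannot interpret posterior samples object", call. = FALSE)
}
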