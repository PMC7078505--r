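# Local and global sensitivity analysis over the 11 tunable parameters
# (NP radius/density/degradation, tumor flow/viscosity/vascular fraction/
# pore radius/porosity, MPS macrophage area fractions, hematocrit) and the
# four AUC outputs (plasma, MPS, tumor interstitium, excreta).

#' Sensitivity parameter space
#'
#' The 11 analysed parameters with their reference values and the uniform
#' perturbation range of +/- 99% around each reference
#' (`[0.01, 1.99] * ref`). The hematocrit upper bound is additionally
#' capped below 1.
#'
#' @return Data frame with `parameter`, `ref`, `lower`, `upper`.
#' @export
sensitivity_space <- function() {
  ref <- c(r = 50, rho_np = 2, k_deg = 0.01,
           Q_T = 0.1, mu_T = 7.42, f_vT = 0.1, r_pore_T = 850, phi = 0.001,
           A_mac_L = 0.5, A_mac_S = 0.1, H = 0.45)
  out <- data.frame(parameter = names(ref), ref = unname(ref),
                    lower = unname(ref) * 0.01, upper = unname(ref) * 1.99)
  out$upper[out$parameter == "H"] <- min(out$upper[out$parameter == "H"],
                                         0.999)
  out
}

#' Model runner over the sensitivity parameter space
#'
#' Returns a function mapping a named vector of (a subset of) the 11
#' sensitivity parameters onto a full tumor-bearing simulation and its
#' four headline AUC outputs. Parameters not supplied stay at their
#' reference values.
#'
#' @param body Base [default_body()].
#' @param tumor Base [default_tumor()].
#' @param np Base [nanoparticle()] (reference 100 nm, density 2,
#'   k_deg 0.01).
#' @param config [sim_config()] used for every evaluation.
#' @return `function(pars)` returning
#'   `c(plasma =, mps =, tumor =, excreta =)` in %ID h.
#' @export
pbpk_output_runner <- function(body = default_body(),
                               tumor = default_tumor(),
                               np = nanoparticle(diameter_nm = 100),
                               config = sim_config()) {
  force(body); force(tumor); force(np); force(config)
  function(pars) {
    p <- as.list(pars)
    # exact [[ indexing: `$` partial matching would let e.g. "r" pick up
    # "r_pore_T" when only the latter is perturbed
    g <- function(key, fallback) {
      v <- p[[key]]
      if (is.null(v)) fallback else v
    }
    np2 <- nanoparticle(
      radius_nm = g("r", np$r_nm),
      density_g_cm3 = g("rho_np", np$rho_np),
      k_deg_per_h = g("k_deg", np$k_deg)
    )
    body2 <- body
    body2$H <- g("H", body$H)
    body2$organs$A_mac[body2$organs$name == "liver"] <-
      g("A_mac_L", body$organs$A_mac[body$organs$name == "liver"])
    body2$organs$A_mac[body2$organs$name == "spleen"] <-
      g("A_mac_S", body$organs$A_mac[body$organs$name == "spleen"])
    tumor2 <- tumor
    tumor2$Q_specific <- g("Q_T", tumor$Q_specific)
    tumor2$mu <- g("mu_T", tumor$mu)
    tumor2$f_v <- g("f_vT", tumor$f_v)
    tumor2$r_pore <- g("r_pore_T", tumor$r_pore)
    tumor2$phi <- g("phi", tumor$phi)
    res <- pbpk_simulate(np2, body2, tumor2, config)
    agg <- aggregate_outputs(res)
    c(plasma = agg$plasma, mps = agg$mps, tumor = agg$tumor,
      excreta = agg$excreta)
  }
}

#' Local sensitivity scan
#'
#' One-at-a-time perturbation of each parameter over `n_levels` equally
#' spaced values on `[lower, upper]` (the exact reference point excluded),
#' measuring the sensitivity coefficient
#' `SC = [(AUC' - AUC) / AUC] / [(Par' - Par) / Par]`
#' for every output, and ranking parameters per output by the maximum
#' `|SC|` over the scan (rank 1 = most influential; ties broken by
#' parameter order). Outputs whose reference AUC is zero are flagged and
#' excluded from ranking.
#'
#' @param runner Model runner as from [pbpk_output_runner()]: a function
#'   of a named parameter vector returning a named output vector.
#' @param space Parameter space (data frame with `parameter`, `ref`,
#'   `lower`, `upper`); default [sensitivity_space()].
#' @param n_levels Number of perturbation levels per parameter.
#' @return List of class `lsa_result`: `curves` (long data frame with
#'   `parameter`, `output`, `level`, `par_value`, `auc`, `sc`), `max_abs`
#'   (parameter x output matrix of max |SC|), `ranks` (same shape),
#'   `reference` (named reference outputs), `undefined_outputs`.
#' @export
lsa_scan <- function(runner, space = sensitivity_space(), n_levels = 1000) {
  ref_out <- runner(stats::setNames(space$ref, space$parameter))
  outs <- names(ref_out)
  undef <- outs[ref_out == 0]
  curves <- vector("list", nrow(space))
  for (i in seq_len(nrow(space))) {
    par <- space$parameter[i]
    ref <- space$ref[i]
    lev <- seq(space$lower[i], space$upper[i], length.out = n_levels)
    lev <- lev[abs(lev / ref - 1) > 1e-12]
    rows <- lapply(seq_along(lev), function(j) {
      out <- runner(stats::setNames(lev[j], par))
      sc <- ifelse(ref_out == 0, NA_real_,
                   ((out - ref_out) / ref_out) / ((lev[j] - ref) / ref))
      data.frame(parameter = par, output = outs, level = j,
                 par_value = lev[j], auc = unname(out), sc = unname(sc))
    })
    curves[[i]] <- do.call(rbind, rows)
  }
  curves <- do.call(rbind, curves)
  max_abs <- with(curves,
                  tapply(abs(sc), list(parameter, output),
                         function(x) if (all(is.na(x))) NA_real_
                         else max(abs(x), na.rm = TRUE)))
  max_abs <- max_abs[space$parameter, outs, drop = FALSE]
  ranks <- vapply(seq_len(ncol(max_abs)), function(j) {
    x <- max_abs[, j]
    r <- rep(NA_integer_, length(x))
    ok <- !is.na(x)
    r[ok] <- rank(-x[ok], ties.method = "first")
    r
  }, integer(nrow(max_abs)))
  ranks <- matrix(ranks, nrow = nrow(max_abs),
                  dimnames = dimnames(max_abs))
  structure(list(curves = curves, max_abs = max_abs, ranks = ranks,
                 reference = ref_out, undefined_outputs = undef),
            class = "lsa_result")
}

#' Latin hypercube designs over the parameter space
#'
#' Per replicate, an `n x k` Latin hypercube design: each parameter range
#' is split into `n` equal strata with exactly one draw per stratum and
#' independently permuted columns. Reproducible for a given seed; the
#' replicate designs are consecutive substreams of the same master seed.
#'
#' @param space Parameter space data frame.
#' @param n Samples per replicate.
#' @param replicates Number of independent designs.
#' @param seed Master RNG seed.
#' @return List of `n x k` matrices with parameter column names.
#' @export
lhs_sample <- function(space, n = 5000, replicates = 10, seed = 42) {
  if (n < 2) stop("need at least two samples", call. = FALSE)
  k <- nrow(space)
  set.seed(seed)
  lapply(seq_len(replicates), function(rep) {
    u <- lhs::randomLHS(n, k)
    x <- sweep(u, 2, space$upper - space$lower, `*`)
    x <- sweep(x, 2, space$lower, `+`)
    colnames(x) <- space$parameter
    x
  })
}

#' Standardised multivariate linear regression sensitivity indices
#'
#' Ordinary least squares of the z-scored output on the z-scored
#' parameters; the sensitivity index is the absolute standardised
#' regression coefficient.
#'
#' @param X `n x k` design matrix of sampled parameter values.
#' @param y Output vector of length `n`.
#' @return Named vector of indices.
#' @export
gsa_mlra <- function(X, y) {
  Z <- scale(X)
  if (any(!is.finite(Z))) stop("constant or degenerate column", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, Z), as.vector(scale(y)))
  if (fit$rank < ncol(X) + 1) stop("rank-deficient design", call. = FALSE)
  stats::setNames(abs(fit$coefficients[-1]), colnames(X))
}

#' Partial rank correlation sensitivity indices
#'
#' Rank-transforms all columns and the output, then for each parameter
#' correlates the residuals of that parameter and of the output after
#' regressing both on the remaining parameters. The index is the absolute
#' partial rank correlation coefficient; invariant under strictly monotone
#' transforms of the output.
#'
#' @inheritParams gsa_mlra
#' @return Named vector of indices (all in `[0, 1]`).
#' @export
gsa_prca <- function(X, y) {
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant column: partial rank correlation undefined", call. = FALSE)
  Xr <- apply(X, 2, rank)
  yr <- rank(y)
  k <- ncol(X)
  si <- vapply(seq_len(k), function(j) {
    other <- cbind(1, Xr[, -j, drop = FALSE])
    rx <- stats::lm.fit(other, Xr[, j])$residuals
    ry <- stats::lm.fit(other, yr)$residuals
    abs(stats::cor(rx, ry))
  }, 0)
  stats::setNames(si, colnames(X))
}

#' One-way ANOVA F sensitivity indices
#'
#' Discretises each parameter's sampled values into `n_bins` equal-count
#' levels and uses the one-way ANOVA F statistic of the output across the
#' levels as the sensitivity index.
#'
#' @inheritParams gsa_mlra
#' @param n_bins Number of equal-count levels (default quartiles).
#' @return Named vector of F values.
#' @export
gsa_anova <- function(X, y, n_bins = 4) {
  si <- vapply(seq_len(ncol(X)), function(j) {
    br <- stats::quantile(X[, j], probs = seq(0, 1, length.out = n_bins + 1))
    g <- cut(X[, j], breaks = unique(br), include.lowest = TRUE)
    if (nlevels(droplevels(g)) < 2)
      stop("degenerate binning for parameter ", colnames(X)[j], call. = FALSE)
    stats::anova(stats::lm(y ~ g))[["F value"]][1]
  }, 0)
  stats::setNames(si, colnames(X))
}

#' Full global sensitivity workflow
#'
#' Latin hypercube sampling of the parameter space, one simulation per
#' sampled parameter set, and the three sensitivity techniques (MLRA,
#' PRCA, ANOVA) per replicate and output, followed by Tukey-grouped
#' weighted ranking (see [gsa_weighted_rank()]).
#'
#' @param runner Model runner (named parameter vector -> named outputs).
#' @param space Parameter space data frame.
#' @param n Samples per replicate (paper-scale default 5000).
#' @param replicates Number of replicate designs (paper-scale default 10).
#' @param seed Master RNG seed.
#' @param n_bins ANOVA binning, see [gsa_anova()].
#' @return List of class `gsa_result`: `si` — nested list
#'   `[[technique]][[output]]` of replicate x parameter index matrices;
#'   `ranking` — per-output result of [gsa_weighted_rank()]; `designs`;
#'   `outputs` (list of replicate output matrices); `seed`.
#' @export
gsa_run <- function(runner, space = sensitivity_space(), n = 5000,
                    replicates = 10, seed = 42, n_bins = 4) {
  designs <- lhs_sample(space, n = n, replicates = replicates, seed = seed)
  out_names <- names(runner(stats::setNames(space$ref, space$parameter)))
  outputs <- lapply(designs, function(X) {
    M <- matrix(NA_real_, nrow(X), length(out_names),
                dimnames = list(NULL, out_names))
    for (i in seq_len(nrow(X))) M[i, ] <- runner(X[i, ])[out_names]
    M
  })
  techniques <- list(mlra = gsa_mlra, prca = gsa_prca,
                     anova = function(X, y) gsa_anova(X, y, n_bins))
  si <- lapply(techniques, function(f) {
    per_out <- lapply(out_names, function(on) {
      t(vapply(seq_along(designs),
               function(r) f(designs[[r]], outputs[[r]][, on]),
               stats::setNames(numeric(nrow(space)), space$parameter)))
    })
    stats::setNames(per_out, out_names)
  })
  ranking <- stats::setNames(lapply(out_names, function(on) {
    gsa_weighted_rank(lapply(si, `[[`, on))
  }), out_names)
  structure(list(si = si, ranking = ranking, designs = designs,
                 outputs = outputs, seed = seed),
            class = "gsa_result")
}

#' Tukey-grouped weighted parameter ranking
#'
#' Per technique, parameters are ordered by the mean absolute sensitivity
#' index across replicates; Tukey's HSD on a one-way ANOVA of the indices
#' (parameter as factor) assigns tied ranks to parameters that are not
#' statistically distinguishable (alpha = 0.05) from the leader of their
#' group. The final rank is the average of the three per-technique ranks,
#' re-ranked (equal technique weights).
#'
#' @param si_by_technique Named list (one element per technique) of
#'   replicate x parameter matrices of sensitivity indices.
#' @param alpha Tukey significance level for declaring two parameters
#'   distinguishable.
#' @return Data frame with `parameter`, one rank column per technique,
#'   `mean_rank` and `final_rank`.
#' @export
gsa_weighted_rank <- function(si_by_technique, alpha = 0.05) {
  if (length(si_by_technique) < 1) stop("no techniques given", call. = FALSE)
  if (any(vapply(si_by_technique, nrow, 0L) < 2))
    stop("need at least two replicates per technique", call. = FALSE)
  params <- colnames(si_by_technique[[1]])
  tech_ranks <- lapply(si_by_technique, function(M) {
    M <- abs(M)
    means <- colMeans(M)
    ord <- order(-means)
    df <- data.frame(
      si = as.vector(M),
      parameter = factor(rep(colnames(M), each = nrow(M)), levels = params)
    )
    tk <- stats::TukeyHSD(stats::aov(si ~ parameter, data = df))$parameter
    p_between <- function(a, b) {
      key <- paste(a, b, sep = "-")
      key2 <- paste(b, a, sep = "-")
      if (key %in% rownames(tk)) tk[key, "p adj"] else tk[key2, "p adj"]
    }
    rk <- numeric(length(params))
    group_head <- ord[1]; group_rank <- 1
    rk[ord[1]] <- 1
    for (pos in seq_along(ord)[-1]) {
      j <- ord[pos]
      if (p_between(params[group_head], params[j]) > alpha) {
        rk[j] <- group_rank         # indistinguishable from group leader
      } else {
        group_head <- j; group_rank <- pos
        rk[j] <- pos
      }
    }
    stats::setNames(rk, params)
  })
  R <- do.call(cbind, tech_ranks)
  mean_rank <- rowMeans(R)
  out <- data.frame(parameter = params, R, mean_rank = mean_rank,
                    final_rank = rank(mean_rank, ties.method = "average"),
                    row.names = NULL)
  out[order(out$final_rank), ]
}
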