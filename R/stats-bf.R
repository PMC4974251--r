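# Default-prior (JZS) Bayes factors for factorial designs.
#
# Fixed effects enter through orthonormal sum-to-zero contrasts with a
# zero-centered g-prior on the standardized coefficients, g ~
# InvGamma(1/2, r^2/2) (one g per model term, scale r_fixed); the subject
# blocking term uses its own g with scale r_random. Under this coding a
# two-level within factor collapsed to within-pair differences is exactly
# the JZS one-sample t Bayes factor with Cauchy scale r_fixed, which is the
# quadrature path below. General models are integrated over their g vector
# by fixed-seed Monte Carlo with the prior as proposal, with a reported
# Monte-Carlo standard error.

#' Enumerate factorial models under full marginality
#'
#' All hierarchical models over the given fixed factors in which every
#' interaction requires all its lower-order constituent terms; the subject
#' blocking term is implicit in every model. The null model (subject term
#' only) is the empty term set. 1, 2 and 3 factors yield 2, 5 and 19
#' models respectively.
#'
#' @param factors character vector of fixed factor names.
#' @return list of character vectors of model terms (`"A"`, `"A:B"`, ...);
#'   first element is the null model (length 0).
#' @export
enumerate_models <- function(factors) {
  stopifnot(length(factors) >= 1)
  k <- length(factors)
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(factors, m, simplify = FALSE)), recursive = FALSE)
  term_name <- function(s) paste(s, collapse = ":")
  nt <- length(subsets)
  models <- list(character(0))
  for (code in seq_len(2^nt - 1)) {
    inc <- as.logical(bitwAnd(code, 2^(seq_len(nt) - 1)))
    terms <- subsets[inc]
    ok <- TRUE
    for (s in terms) {
      if (length(s) > 1) {
        for (m in seq_len(length(s) - 1)) {
          subs <- utils::combn(s, m, simplify = FALSE)
          if (!all(vapply(subs, function(x)
            term_name(x) %in% vapply(terms, term_name, ""), logical(1)))) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) break
    }
    if (ok) models[[length(models) + 1]] <- vapply(terms, term_name, "")
  }
  models
}

# Orthonormal sum-to-zero contrast matrix for a factor with a levels:
# eigenvectors of the centering matrix I - J/a (a-1 columns, unit norm).
orthonormal_contrasts <- function(a) {
  C <- diag(a) - 1 / a
  e <- eigen(C, symmetric = TRUE)
  e$vectors[, seq_len(a - 1), drop = FALSE]
}

# Design matrix columns for one model term ("A" or "A:B"); one column per
# degree of freedom, products of the per-factor contrast codes.
term_columns <- function(term, data) {
  facs <- strsplit(term, ":", fixed = TRUE)[[1]]
  cols <- matrix(1, nrow(data), 1)
  for (f in facs) {
    lev <- sort(unique(as.character(data[[f]])))
    Q <- orthonormal_contrasts(length(lev))
    code <- Q[match(as.character(data[[f]]), lev), , drop = FALSE]
    cols <- do.call(cbind, lapply(seq_len(ncol(code)), function(j)
      cols * code[, j]))
  }
  cols
}

# Subject indicator columns (full dummy coding; centered later with the rest).
subject_columns <- function(data, subject = "subject") {
  s <- factor(data[[subject]])
  stats::model.matrix(~ s - 1)
}

# log of the conditional Bayes factor BF(g) of a linear model with prior
# covariance sigma^2 * diag(gexp) against the no-covariate model, after
# integrating out intercept and sigma^2 (Jeffreys prior). All columns and y
# are centered. Precomputed: XtX, Xty, yty, nu = N - 1.
log_bf_given_g <- function(gexp, XtX, Xty, yty, nu) {
  A <- XtX + diag(1 / gexp, length(gexp))
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- sum(log(gexp)) + 2 * sum(log(diag(R)))
  # degenerate response (constant y): only the Occam penalty remains
  if (yty <= 1e-300) return(-0.5 * logdet)
  z <- backsolve(R, Xty, transpose = TRUE)
  quad <- max(yty - sum(z^2), 1e-12 * yty)
  -0.5 * logdet - (nu / 2) * (log(quad) - log(yty))
}

# Prior draw: g ~ InvGamma(1/2, r^2/2)  <=>  g = r^2 / chisq_1.
rinvgamma_g <- function(n, r) r^2 / stats::rchisq(n, df = 1)

dinvgamma_g <- function(g, r) {
  # density of InvGamma(shape 1/2, scale r^2/2)
  (r^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
}

# Marginal log BF (vs no-covariate model) of a one-g design by adaptive
# quadrature over u = log g.
log_bf_one_g_quad <- function(XtX, Xty, yty, nu, r) {
  p <- nrow(XtX)
  f <- function(u) {
    vapply(u, function(ui) {
      g <- exp(ui)
      exp(log_bf_given_g(rep(g, p), XtX, Xty, yty, nu)) *
        dinvgamma_g(g, r) * g
    }, numeric(1))
  }
  v <- stats::integrate(f, lower = -30, upper = 30, rel.tol = 1e-9,
                        subdivisions = 400L)
  log(v$value)
}

#' JZS Bayes factor of a one-sample (paired) t design
#'
#' Closed-form one-dimensional integral of the JZS Bayes factor for a
#' one-sample mean against zero with a Cauchy(`rscale`) prior on the
#' standardized effect, evaluated by adaptive quadrature over log g.
#'
#' @param t t statistic.
#' @param n sample size (pairs).
#' @param rscale Cauchy prior scale.
#' @return log Bayes factor (alternative vs null).
#' @export
jzs_ttest_bf <- function(t, n, rscale = 0.5) {
  nu <- n - 1
  log_null <- -((nu + 1) / 2) * log1p(t^2 / nu)
  f <- function(u) {
    vapply(u, function(ui) {
      g <- exp(ui)
      la <- -0.5 * log1p(n * g) -
        ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu))
      exp(la - log_null) * dinvgamma_g(g, rscale) * g
    }, numeric(1))
  }
  v <- stats::integrate(f, lower = -35, upper = 35, rel.tol = 1e-10,
                        subdivisions = 500L)
  log(v$value)
}

# Build centered response and per-term design blocks for one model.
build_design <- function(table, terms, subject = "subject", dv = "value") {
  y <- table[[dv]]
  y <- y - mean(y)
  blocks <- lapply(terms, term_columns, data = table)
  Xs <- subject_columns(table, subject)
  X <- do.call(cbind, c(blocks, list(Xs)))
  X <- sweep(X, 2, colMeans(X))
  group <- c(rep(seq_along(terms), vapply(blocks, ncol, 0L)),
             rep(length(terms) + 1L, ncol(Xs)))
  list(y = y, X = X, group = group, n_terms = length(terms))
}

#' JZS Bayes factor of one factorial model against the subject-only null
#'
#' Computes the default-prior Bayes factor of a model (a set of factorial
#' terms from [enumerate_models()]) against the null model containing only
#' the subject blocking term. Each model term gets its own g with prior
#' scale `r_fixed`; the subject term's g has scale `r_random`. The marginal
#' likelihood is integrated over the g vector by fixed-seed Monte Carlo with
#' the prior as proposal (reported with its Monte-Carlo standard error); the
#' one-g marginals (and, via `method = "quadrature"`, single two-level
#' within-factor models collapsed to difference scores) are evaluated by
#' one-dimensional adaptive quadrature.
#'
#' @param table long-format table for one measure: `subject`, `value`, and
#'   the factor columns.
#' @param model character vector of model terms (possibly empty = null).
#' @param r_fixed,r_random prior scales for fixed terms and the subject term.
#' @param draws Monte-Carlo draws.
#' @param seed integer seed for the Monte-Carlo integration.
#' @param method `"auto"` chooses the collapsed quadrature path for a
#'   single two-level within factor and Monte Carlo otherwise.
#' @param dv value column name.
#' @return list with `logbf` (vs the subject-only null), `mcse`, `method`,
#'   `draws`, `seed`.
#' @export
jzs_bf <- function(table, model, r_fixed = 0.5, r_random = 1.0,
                   draws = 10000, seed = 1,
                   method = c("auto", "mc", "quadrature"), dv = "value") {
  method <- match.arg(method)
  if (!length(model)) {
    return(list(logbf = 0, mcse = 0, method = "null", draws = 0L, seed = seed))
  }
  collapsible <- length(model) == 1 && !grepl(":", model) &&
    length(unique(table[[model]])) == 2 &&
    all(table(table$subject, table[[model]]) == 1)
  if (method == "quadrature" && !collapsible) {
    stopf("quadrature path requires a single two-level within factor")
  }
  if (collapsible && method != "mc") {
    # collapse to within-pair differences scaled to unit error variance:
    # d_i = (y_i1 - y_i2)/sqrt(2); the orthonormal-contrast model prior on
    # the standardized difference is then exactly Cauchy(r_fixed).
    lev <- sort(unique(as.character(table[[model]])))
    wide <- split(table, table$subject)
    d <- vapply(wide, function(df) {
      (mean(df[[dv]][df[[model]] == lev[1]]) -
         mean(df[[dv]][df[[model]] == lev[2]])) / sqrt(2)
    }, numeric(1))
    n <- length(d)
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    return(list(logbf = jzs_ttest_bf(t, n, r_fixed), mcse = 0,
                method = "quadrature", draws = 0L, seed = seed))
  }

  des <- build_design(table, model)
  XtX <- crossprod(des$X)
  Xty <- crossprod(des$X, des$y)[, 1]
  yty <- sum(des$y^2)
  nu <- length(des$y) - 1
  scales <- c(rep(r_fixed, des$n_terms), r_random)

  # null model: subject term only, one g -> quadrature
  null_des <- build_design(table, character(0))
  n_XtX <- crossprod(null_des$X)
  n_Xty <- crossprod(null_des$X, null_des$y)[, 1]
  log_null <- log_bf_one_g_quad(n_XtX, n_Xty, yty, nu, r_random)

  ng <- des$n_terms + 1L
  lb <- with_seed(split_seed(seed, 17L), {
    gmat <- matrix(rinvgamma_g(draws * ng, 1), draws, ng)
    gmat <- sweep(gmat, 2, scales^2, "*")
    vapply(seq_len(draws), function(i) {
      log_bf_given_g(gmat[i, des$group], XtX, Xty, yty, nu)
    }, numeric(1))
  })
  m <- max(lb)
  w <- exp(lb - m)
  log_num <- m + log(mean(w))
  mcse <- stats::sd(w) / sqrt(draws) / mean(w)  # relative se -> se of log
  list(logbf = log_num - log_null, mcse = mcse, method = "mc",
       draws = draws, seed = seed)
}

#' Bayes-factor model comparison over a factorial design
#'
#' Enumerates all models under full marginality, computes each model's JZS
#' Bayes factor against the subject-only null, and reports (a) the
#' strongest model overall, (b) the strongest model containing the
#' stimulation factor, and the two summary ratios: the subject-only null
#' versus (b), and the strongest stimulation-free model versus (b) (the
#' "stimulation exclusion ratio" -- the evidence against any stimulation
#' effect given the task structure).
#'
#' @param table long-format table for one measure.
#' @param factors fixed factors to enumerate over.
#' @param stim_factor name of the stimulation factor.
#' @param r_fixed,r_random prior scales.
#' @param draws,seed Monte-Carlo settings per model.
#' @param mcse_tol flag threshold for non-converged Monte-Carlo error (on
#'   the log Bayes factor).
#' @param dv value column name.
#' @return a `bayes_factor_result`: data.frame of models (terms, `logbf`,
#'   `mcse`, `flagged`) with attributes `strongest`, `strongest_stim`,
#'   `ratio_null_vs_stim` (null / best-stim Bayes factor),
#'   `ratio_exclusion` (best stim-free / best-stim), `r_fixed`, `r_random`,
#'   `seed`.
#' @export
model_comparison <- function(table, factors, stim_factor = "stimulation",
                             r_fixed = 0.5, r_random = 1.0,
                             draws = 10000, seed = 1, mcse_tol = 0.2,
                             dv = "value") {
  models <- enumerate_models(factors)
  labels <- vapply(models, function(m)
    if (!length(m)) "null" else paste(m, collapse = " + "), "")
  fits <- lapply(seq_along(models), function(i)
    jzs_bf(table, models[[i]], r_fixed, r_random, draws,
           seed = split_seed(seed, i), dv = dv))
  logbf <- vapply(fits, `[[`, 0, "logbf")
  mcse <- vapply(fits, `[[`, 0, "mcse")
  has_stim <- vapply(models, function(m)
    any(stim_factor %in% unlist(strsplit(m, ":"))), logical(1))
  res <- data.frame(model = labels, logbf = logbf, mcse = mcse,
                    has_stim = has_stim, flagged = mcse > mcse_tol,
                    stringsAsFactors = FALSE)
  best <- which.max(logbf)
  best_stim <- which(has_stim)[which.max(logbf[has_stim])]
  best_free <- which(!has_stim)[which.max(logbf[!has_stim])]
  structure(res,
            strongest = labels[best],
            strongest_stim = labels[best_stim],
            ratio_null_vs_stim = exp(-logbf[best_stim]),
            ratio_exclusion = exp(logbf[best_free] - logbf[best_stim]),
            r_fixed = r_fixed, r_random = r_random, seed = seed,
            class = c("bayes_factor_result", "data.frame"))
}
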