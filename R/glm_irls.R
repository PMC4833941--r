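# First-principles GLM fitting for the two models the pathway analysis uses:
# logistic regression (expected events) and modified Poisson regression
# (log-link Poisson on a binary outcome, yielding risk ratios), with
# cluster-robust sandwich covariance. Fitting is by iteratively reweighted
# least squares (IRLS); both links are canonical for their families, so the
# score is X'(y - mu) and the expected information X'WX with W = mu(1-mu)
# (logit) or W = mu (log).

#' Fit a binary-outcome GLM by IRLS
#'
#' @param formula model formula; the response must be 0/1.
#' @param data data frame; rows with missing values in any model variable are
#'   dropped (complete-case) and the count is recorded.
#' @param link `"logit"` for logistic regression or `"log"` for modified
#'   Poisson regression (log-link Poisson applied to a binary outcome, valid
#'   by construction for risk-ratio estimation when paired with a robust
#'   variance).
#' @param cluster optional cluster id vector (length `nrow(data)`) or the
#'   name of a column in `data`; when given, the cluster-robust sandwich
#'   covariance is attached.
#' @param tol relative coefficient-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `crt_glm`: coefficients, model-based and (if
#'   clustered) robust covariances, fitted means, convergence record, counts
#'   of observations, clusters, dropped rows, and (log link) fitted means
#'   above 1.
#' @export
fit_glm <- function(formula, data, link = c("logit", "log"), cluster = NULL,
                    tol = 1e-8, max_iter = 100L) {
  link <- match.arg(link)
  if (is.character(cluster) && length(cluster) == 1L) {
    if (!cluster %in% names(data)) stop("no cluster column '", cluster, "'")
    cluster <- data[[cluster]]
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  n_dropped <- sum(!keep)
  mf <- mf[keep, , drop = FALSE]
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be 0/1")
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!is.null(cluster)) cluster <- cluster[keep]
  if (sum(y) == 0L || sum(y) == length(y))
    stop("response has no events or no non-events after filtering")

  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  fit <- irls(x, y, link, tol = tol, max_iter = max_iter)
  fit$formula <- formula
  fit$link <- link
  fit$n <- length(y)
  fit$n_dropped <- n_dropped
  fit$rows_used <- which(keep)
  fit$y <- y
  fit$x <- x
  if (link == "log") fit$n_mu_above_1 <- sum(fit$mu > 1)
  if (!is.null(cluster)) {
    fit$cluster <- cluster
    rb <- cluster_robust_vcov(fit, cluster)
    fit$vcov_robust <- rb$corrected
    fit$vcov_robust_uncorrected <- rb$uncorrected
    fit$n_clusters <- rb$n_clusters
  }
  class(fit) <- "crt_glm"
  fit
}

irls <- function(x, y, link, tol = 1e-8, max_iter = 100L) {
  deviance_of <- function(mu) {
    if (link == "logit")
      -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    else
      -2 * sum(y * log(pmax(mu, 1e-12)) - mu)
  }
  mu_of <- function(eta) {
    if (link == "logit") stats::plogis(eta) else exp(pmin(eta, 30))
  }
  if (link == "logit") {
    mu <- (y + 0.5) / 2
    eta <- stats::qlogis(mu)
  } else {
    mu <- pmax(y, 0) + 0.1
    eta <- log(mu)
  }
  beta <- NULL
  dev <- deviance_of(mu_of(eta))
  step_norm <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    mu <- mu_of(eta)
    w <- if (link == "logit") mu * (1 - mu) else mu
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    qrf <- qr(x * sw)
    beta_new <- qr.coef(qrf, z * sw)
    if (any(!is.finite(beta_new)))
      stop("IRLS diverged (non-finite coefficients) at iteration ", it,
           "; possible separation. Step norms: ",
           paste(signif(trace, 3), collapse = ", "))
    # step-halving towards the previous iterate when the deviance worsens
    # (log-link fits on binary data can oscillate without it)
    if (!is.null(beta)) {
      half <- 0L
      while (deviance_of(mu_of(drop(x %*% beta_new))) > dev + 1e-10 &&
               half < 30L) {
        beta_new <- (beta_new + beta) / 2
        half <- half + 1L
      }
    }
    step_norm <- if (is.null(beta)) Inf else
      max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    trace <- c(trace, step_norm)
    beta <- beta_new
    eta <- drop(x %*% beta)
    dev <- deviance_of(mu_of(eta))
    if (step_norm < tol) break
  }
  if (step_norm >= tol)
    stop("IRLS failed to converge in ", max_iter,
         " iterations (final relative step ", signif(step_norm, 3),
         "); possible separation")
  if (link == "logit") {
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
  } else {
    mu <- exp(eta)
    w <- mu
  }
  xtwx <- crossprod(x * sqrt(pmax(w, 1e-12)))
  vcov_model <- chol2inv(chol(xtwx))
  dimnames(vcov_model) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)
  list(coefficients = beta, vcov_model = vcov_model, mu = mu, eta = eta,
       weights = w, iterations = it, final_step = step_norm,
       info = xtwx)
}

#' Cluster-robust sandwich covariance for a fitted GLM
#'
#' Computes `A^{-1} B A^{-1}` where `A` is the expected information `X'WX`
#' and `B` the outer-product sum of per-cluster score vectors
#' `sum_g s_g s_g'`, `s_g = sum_{i in g} x_i (y_i - mu_i)`. Returns both the
#' plain estimator and the small-sample corrected form multiplied by
#' `G/(G-1)` (G = number of clusters), the default used for inference.
#'
#' @param fit a `crt_glm` (or the list returned by the internal IRLS).
#' @param cluster cluster id vector aligned with the rows used in the fit.
#' @return list with `corrected`, `uncorrected`, `n_clusters`.
#' @export
cluster_robust_vcov <- function(fit, cluster) {
  cluster <- as.character(cluster)
  G <- length(unique(cluster))
  if (G < 2L) stop("cluster-robust variance needs >= 2 clusters, got ", G)
  scores <- fit$x * (fit$y - fit$mu)
  sg <- rowsum(scores, cluster)
  meat <- crossprod(as.matrix(sg))
  bread <- chol2inv(chol(fit$info))
  v <- bread %*% meat %*% bread
  dimnames(v) <- dimnames(fit$vcov_model)
  list(corrected = v * G / (G - 1), uncorrected = v, n_clusters = G)
}

#' @export
print.crt_glm <- function(x, ...) {
  cat(sprintf("GLM (%s link) fitted by IRLS: n = %d, %d iterations\n",
              x$link, x$n, x$iterations))
  if (!is.null(x$n_clusters))
    cat(sprintf("  cluster-robust covariance over %d clusters\n", x$n_clusters))
  print(x$coefficients)
  invisible(x)
}

#' Risk ratio (or odds ratio) for one model term
#'
#' Exponentiates the term's coefficient with a Wald CI on the log scale,
#' using the small-sample corrected cluster-robust SE when available and the
#' model-based SE otherwise.
#'
#' @param fit a `crt_glm`.
#' @param term coefficient name.
#' @param level confidence level.
#' @param vcov_type `"robust"` (default; corrected), `"robust-uncorrected"`,
#'   or `"model"`.
#' @return an `effect_estimate`: data frame row with term, estimate, lower,
#'   upper, se_log, n, n_clusters, and a degenerate-CI flag.
#' @export
risk_ratio_from_model <- function(fit, term, level = 0.95,
                                  vcov_type = c("robust", "robust-uncorrected",
                                                "model")) {
  vcov_type <- match.arg(vcov_type)
  if (!term %in% names(fit$coefficients))
    stop("term '", term, "' not in model (have: ",
         paste(names(fit$coefficients), collapse = ", "), ")")
  v <- switch(vcov_type,
              robust = fit$vcov_robust,
              `robust-uncorrected` = fit$vcov_robust_uncorrected,
              model = fit$vcov_model)
  if (is.null(v)) {
    if (vcov_type != "model")
      stop("no cluster-robust covariance on this fit; pass cluster= to fit_glm")
  }
  b <- fit$coefficients[[term]]
  se <- sqrt(v[term, term])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(term = term, estimate = exp(b),
                    lower = exp(b - zq * se), upper = exp(b + zq * se),
                    se_log = se, n = fit$n,
                    n_clusters = fit$n_clusters %||% NA_integer_,
                    degenerate = se < 1e-10,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Screen for intervention-by-risk-factor interaction
#'
#' Adds the product of the arm and risk-factor terms to the model and tests
#' it with a Wald test on the cluster-robust covariance. When the product is
#' inestimable (collinear with main effects, e.g. the risk factor equals the
#' arm indicator), the interaction is reported as untestable rather than
#' tested.
#'
#' @param formula base model formula (without the interaction).
#' @param data data frame.
#' @param arm,risk_factor names of the two columns to interact.
#' @param cluster cluster id column name or vector.
#' @param link model link (default `"log"`, modified Poisson).
#' @param alpha flag threshold.
#' @return list with testable, p_value, estimate (interaction log-RR), flag.
#' @export
interaction_screen <- function(formula, data, arm = "arm", risk_factor,
                               cluster, link = "log", alpha = 0.05) {
  f_int <- stats::update(formula,
                         paste(". ~ . +", arm, ":", risk_factor))
  fit <- tryCatch(
    fit_glm(f_int, data, link = link, cluster = cluster),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    if (grepl("rank deficient|aliased", conditionMessage(fit)))
      return(list(testable = FALSE, p_value = NA_real_, estimate = NA_real_,
                  flag = FALSE, reason = conditionMessage(fit)))
    stop(fit)
  }
  int_terms <- grep(paste0(arm, ".*:|:.*", arm), names(fit$coefficients),
                    value = TRUE)
  int_terms <- int_terms[grepl(risk_factor, int_terms)]
  if (length(int_terms) != 1L)
    return(list(testable = FALSE, p_value = NA_real_, estimate = NA_real_,
                flag = FALSE, reason = "interaction term not identifiable"))
  b <- fit$coefficients[[int_terms]]
  se <- sqrt(fit$vcov_robust[int_terms, int_terms])
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  list(testable = TRUE, p_value = p, estimate = b, se = se,
       flag = p < alpha, term = int_terms)
}
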