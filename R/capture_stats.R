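# Capture-success modeling: candidate GLMs of recovered-locus counts
# (Poisson, log link) and mean locus lengths (Gaussian, identity link) over
# per-taxon covariates, ranked by AIC and combined by Akaike-weight model
# averaging over the valid candidate set (w_i > 0.10).

#' Fit a set of candidate GLMs of capture success
#'
#' @param data data.frame of per-taxon covariates. Responses: `uce_count`
#'   for `response = "count"` (Poisson, log link) and `mean_uce_length` for
#'   `response = "length"` (Gaussian, identity link); override with
#'   `response_col`.
#' @param response `"count"` or `"length"`.
#' @param term_sets list of character vectors of covariate names; an empty
#'   vector (or `"1"`) is the intercept-only model. Term sets must be
#'   distinct.
#' @param response_col optional response column name overriding the default.
#' @return object of class `uce_model_set`: a data.frame with one row per
#'   model (`terms`, `family`, `k`, `log_likelihood`, `aic`), carrying the
#'   fitted models as an attribute. Non-converging fits are dropped with a
#'   warning.
#' @export
fit_model_set <- function(data, response = c("count", "length"), term_sets,
                          response_col = NULL) {
  response <- match.arg(response)
  ycol <- response_col %||% switch(response, count = "uce_count",
                                   length = "mean_uce_length")
  stopifnot(ycol %in% names(data), is.list(term_sets), length(term_sets) >= 1)
  canon <- vapply(term_sets, function(ts) {
    ts <- setdiff(ts, "1")
    if (!length(ts)) "1" else paste(sort(ts), collapse = " + ")
  }, character(1))
  if (anyDuplicated(canon)) stop("duplicate term sets")
  used <- unique(unlist(lapply(term_sets, setdiff, "1")))
  missing_cov <- setdiff(used, names(data))
  if (length(missing_cov)) stop("unknown covariates: ",
                                paste(missing_cov, collapse = ", "))
  if (anyNA(data[, c(ycol, used), drop = FALSE])) {
    stop("missing values in response or covariates")
  }
  fam <- switch(response, count = poisson(link = "log"),
                length = gaussian(link = "identity"))
  fits <- list()
  rows <- NULL
  for (i in seq_along(term_sets)) {
    fml <- stats::reformulate(if (canon[i] == "1") "1" else
      setdiff(term_sets[[i]], "1"), response = ycol)
    fit <- glm(fml, family = fam, data = data)
    if (!fit$converged) {
      warning("model '", canon[i], "' did not converge; excluded")
      next
    }
    ll <- logLik(fit)
    k <- attr(ll, "df")
    rows <- rbind(rows, data.frame(
      terms = canon[i], family = paste0(fam$family, "_", fam$link),
      k = k, log_likelihood = as.numeric(ll), aic = 2 * k - 2 * as.numeric(ll),
      stringsAsFactors = FALSE))
    fits[[canon[i]]] <- fit
  }
  if (is.null(rows)) stop("no model converged")
  structure(rows, fits = fits, response = ycol, class = c("uce_model_set",
                                                          "data.frame"))
}

#' Rank models by AIC and compute Akaike weights
#'
#' Delta_i = AIC_i - min AIC; w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2).
#'
#' @param models a `uce_model_set` (or data.frame with an `aic` column).
#' @return the model set sorted by AIC with `delta_aic` and `weight` added.
#' @export
akaike_weights <- function(models) {
  stopifnot(nrow(models) >= 1, "aic" %in% names(models))
  models$delta_aic <- models$aic - min(models$aic)
  rel <- exp(-models$delta_aic / 2)
  models$weight <- rel / sum(rel)
  o <- order(models$aic)
  out <- models[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- attr(models, "fits")
  attr(out, "response") <- attr(models, "response")
  class(out) <- class(models)
  out
}

#' Model-averaged coefficients over the valid candidate set
#'
#' Models with Akaike weight strictly above `threshold` form the candidate
#' set; their weights are renormalized and coefficients averaged. Under
#' zero-substitution averaging (default) a term absent from a model
#' contributes 0 to the average; `conditional = TRUE` instead renormalizes
#' per term over only the models that contain it.
#'
#' @param models output of [akaike_weights()] on a fitted `uce_model_set`.
#' @param threshold weight threshold, default 0.10.
#' @param conditional use conditional (per-term) averaging.
#' @return data.frame: `term`, `estimate`, `n_models` (candidate models
#'   containing the term).
#' @export
model_average <- function(models, threshold = 0.10, conditional = FALSE) {
  stopifnot("weight" %in% names(models))
  fits <- attr(models, "fits")
  if (is.null(fits)) stop("model set carries no fitted models")
  cand <- models$weight > threshold
  if (!any(cand)) stop("no model exceeds threshold")
  sel <- models[cand, , drop = FALSE]
  w <- sel$weight / sum(sel$weight)
  coefs <- lapply(sel$terms, function(t) coef(fits[[t]]))
  terms_all <- unique(unlist(lapply(coefs, names)))
  est <- vapply(terms_all, function(tm) {
    present <- vapply(coefs, function(cf) tm %in% names(cf), logical(1))
    beta <- vapply(coefs, function(cf) if (tm %in% names(cf)) cf[[tm]] else 0,
                   numeric(1))
    if (conditional) {
      sum(w[present] * beta[present]) / sum(w[present])
    } else {
      sum(w * beta)
    }
  }, numeric(1))
  data.frame(term = terms_all, estimate = unname(est),
             n_models = vapply(terms_all, function(tm) {
               sum(vapply(coefs, function(cf) tm %in% names(cf), logical(1)))
             }, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.uce_model_set <- function(x, ...) {
  cat("Candidate GLMs of capture success (response: ",
      attr(x, "response") %||% "?", ")\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
summary.uce_model_set <- function(object, ...) {
  if (!"weight" %in% names(object)) object <- akaike_weights(object)
  cat("Best model by AIC:", object$terms[1],
      sprintf("(AIC %.2f, weight %.3f)\n", object$aic[1], object$weight[1]))
  invisible(object)
}
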