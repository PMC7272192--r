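# Penalized logistic objective and gradient, liblinear-style scaling:
#   f(w, b) = 0.5 * ||w||^2 + C * sum_i log(1 + exp(-t_i * (x_i'w + b)))
# with t in {-1, +1}; the intercept b is unpenalized.
.logit_obj <- function(par, X, t, C) {
  w <- par[-1L]; b <- par[1L]
  eta <- t * (as.vector(X %*% w) + b)
  0.5 * sum(w^2) + C * sum(log1p(exp(-eta)))
}

.logit_grad <- function(par, X, t, C) {
  w <- par[-1L]; b <- par[1L]
  eta <- t * (as.vector(X %*% w) + b)
  g <- -t * stats::plogis(-eta)       # d loss / d eta * t
  c(C * sum(g), w + C * as.vector(crossprod(X, g)))
}

.train_binary <- function(X, t, C, tol, maxit) {
  fit <- stats::optim(rep(0, ncol(X) + 1L), .logit_obj, .logit_grad,
                      X = X, t = t, C = C, method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  list(intercept = fit$par[1L], weights = fit$par[-1L], value = fit$value,
       converged = fit$convergence == 0L)
}

#' Train one-vs-rest L2-regularized logistic category classifiers
#'
#' One binary logistic model per category (that category vs the rest),
#' minimizing \code{0.5*||w||^2 + C * sum(log-loss)} by BFGS with analytic
#' gradients; the intercept is unpenalized. The problem is convex, so the fit
#' is deterministic given the data and solver settings.
#'
#' @param X trials x voxel matrix of (normalized) localizer patterns.
#' @param labels category label per trial.
#' @param C inverse-penalty parameter (default 0.01).
#' @param categories category order (defines downstream tie-breaking);
#'   defaults to sorted unique labels.
#' @param tol relative convergence tolerance of the solver (default 1e-8).
#' @param maxit maximum BFGS iterations.
#' @return object of class \code{memupdate_classifier}: weights (voxels x
#'   categories), intercepts, categories, C.
#' @export
train_classifier <- function(X, labels, C = 0.01,
                             categories = sort(unique(labels)),
                             tol = 1e-8, maxit = 2000L) {
  if (any(!is.finite(X))) stop("non-finite values in training patterns")
  missing_cat <- setdiff(categories, unique(labels))
  if (length(missing_cat))
    stop("category absent from training labels: ",
         paste(missing_cat, collapse = ", "))
  if (length(categories) < 2L) stop("need at least 2 categories")
  fits <- lapply(categories, function(cat) {
    t <- ifelse(labels == cat, 1, -1)
    .train_binary(X, t, C, tol, maxit)
  })
  structure(list(
    weights = vapply(fits, `[[`, numeric(ncol(X)), "weights"),
    intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
    loss = vapply(fits, `[[`, numeric(1), "value"),
    categories = categories, C = C
  ), class = "memupdate_classifier")
}

#' Per-category probabilities from the one-vs-rest classifiers
#'
#' Each binary model contributes its positive-class probability for its
#' category; by default the per-category probabilities are renormalized to
#' sum to one within each trial (the unnormalized variant is available via
#' \code{renormalize = FALSE}).
#'
#' @param model a \code{\link{train_classifier}} fit.
#' @param X trials x voxel matrix.
#' @param renormalize renormalize to the probability simplex (default TRUE).
#' @return trials x categories matrix of probabilities.
#' @export
predict_probs <- function(model, X, renormalize = TRUE) {
  if (is.vector(X)) X <- matrix(X, 1L)
  if (ncol(X) != nrow(model$weights))
    stop(sprintf("pattern dimension %d does not match model dimension %d",
                 ncol(X), nrow(model$weights)))
  p <- stats::plogis(sweep(X %*% model$weights, 2L, model$intercepts, `+`))
  colnames(p) <- model$categories
  if (renormalize) p <- p / rowSums(p)
  p
}

# Argmax category with ties broken by the model's fixed category order.
predict_category <- function(model, X, renormalize = TRUE) {
  p <- predict_probs(model, X, renormalize)
  model$categories[apply(p, 1L, which.max)]
}

#' Leave-one-run-out cross-validation of the category classifiers
#'
#' For each localizer run, trains on the remaining runs and scores argmax
#' category predictions on the held-out run.
#'
#' @param X trials x voxel matrix.
#' @param labels category label per trial.
#' @param run_ids run index per trial (at least 2 distinct runs).
#' @param C inverse-penalty parameter.
#' @param ... passed to \code{\link{train_classifier}}.
#' @return list with \code{fold_accuracy} (named by run) and
#'   \code{mean_accuracy}.
#' @export
crossvalidate <- function(X, labels, run_ids, C = 0.01, ...) {
  runs <- sort(unique(run_ids))
  if (length(runs) < 2L) stop("leave-one-run-out requires at least 2 runs")
  acc <- vapply(runs, function(r) {
    tr <- run_ids != r
    model <- train_classifier(X[tr, , drop = FALSE], labels[tr], C = C,
                              categories = sort(unique(labels)), ...)
    mean(predict_category(model, X[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1))
  list(fold_accuracy = stats::setNames(acc, paste0("run", runs)),
       mean_accuracy = mean(acc))
}

#' Reassign category probabilities to target/competitor/other evidence
#'
#' For each trial, the probability of the pair's category C becomes the
#' target evidence, the probability of category B the competitor evidence,
#' and the probability of the remaining category the "other" evidence.
#' Normalized evidence subtracts the other evidence within each trial:
#' \code{target_norm = target_ev - other_ev},
#' \code{competitor_norm = competitor_ev - other_ev}.
#'
#' @param probs trials x categories probability matrix (category colnames).
#' @param trials data.frame aligned with \code{probs} rows; must contain
#'   \code{pair_id} (other columns are carried through).
#' @param pairs the pair specification table.
#' @return data.frame: carried trial keys plus \code{prob_<category>} columns,
#'   \code{target_ev}, \code{competitor_ev}, \code{other_ev},
#'   \code{target_norm}, \code{competitor_norm}, \code{predicted_category}.
#' @export
assign_evidence <- function(probs, trials, pairs) {
  if (nrow(probs) != nrow(trials)) stop("probs and trials are misaligned")
  cats <- colnames(probs)
  if (length(cats) != 3L)
    stop("evidence assignment requires exactly 3 categories")
  pi <- match(trials$pair_id, pairs$pair_id)
  if (any(is.na(pi))) stop("trials reference unknown pair_id")
  B <- pairs$category_B[pi]; C <- pairs$category_C[pi]
  if (any(B == C)) stop("pair with category_B == category_C")
  other <- vapply(seq_along(B), function(i) setdiff(cats, c(B[i], C[i])),
                  character(1))
  n <- nrow(probs)
  out <- trials
  for (cat in cats) out[[paste0("prob_", cat)]] <- probs[, cat]
  out$target_ev <- probs[cbind(seq_len(n), match(C, cats))]
  out$competitor_ev <- probs[cbind(seq_len(n), match(B, cats))]
  out$other_ev <- probs[cbind(seq_len(n), match(other, cats))]
  out$target_norm <- out$target_ev - out$other_ev
  out$competitor_norm <- out$competitor_ev - out$other_ev
  out$predicted_category <- cats[apply(probs, 1L, which.max)]
  rownames(out) <- NULL
  out
}

#' Agreement between decoded category and behavioral judgment
#'
#' Fraction of trials on which the classifier's argmax category equals the
#' subject's categorical response, over trials with a category response
#' (dontknow/noresponse excluded).
#'
#' @param predicted_category decoded category per trial.
#' @param responses behavioral response per trial (categories or
#'   dontknow/noresponse).
#' @param categories valid category labels.
#' @return proportion in [0, 1].
#' @export
judgment_prediction_accuracy <- function(predicted_category, responses,
                                         categories = sort(unique(predicted_category))) {
  keep <- responses %in% categories
  if (!any(keep)) stop("no trials with a category response")
  mean(predicted_category[keep] == responses[keep])
}
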