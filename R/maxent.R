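# Binary maximum-entropy classifier.
#
# The exponential-form conditional model p(y|x) proportional to
# exp(sum_i lambda_i f_i(x, y)) with two labels reduces to logistic
# regression on the signed weight vector; training maximizes the
# L2-regularized (Gaussian prior) conditional log-likelihood, a convex
# problem with a unique optimum.  All weights start at 0 and are updated
# iteratively until the gradient norm falls below tolerance.

# numerically stable log(1 + exp(eta))
log1pexp <- function(eta) {
  pmax(eta, 0) + log1p(exp(-abs(eta)))
}

#' Configuration for maximum-entropy training
#'
#' @param l2_variance Variance of the Gaussian (L2) prior on the weights;
#'   smaller values shrink harder.  The bias is not penalized.
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Iteration cap for the optimizer.
#' @return A list of hyperparameters.
#' @export
maxent_config <- function(l2_variance = 1.0, tol = 1e-6, max_iter = 250L) {
  stopifnot(l2_variance > 0, tol > 0, max_iter >= 1)
  list(l2_variance = l2_variance, tol = tol, max_iter = as.integer(max_iter))
}

as_training_matrix <- function(x) {
  if (inherits(x, "feature_vector")) return(fv_as_matrix(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "feature_vector"))) {
    return(do.call(rbind, lapply(x, fv_as_matrix)))
  }
  methods::as(x, "CsparseMatrix")
}

#' Train a binary maximum-entropy model
#'
#' @param pos,neg Positive and negative training documents: sparse
#'   document-term matrices (rows are documents) or lists of
#'   `feature_vector`s over the same vocabulary.
#' @param config Hyperparameters from [maxent_config()].
#' @param vocab Optional vocabulary carried on the model (needed by
#'   [top_features()]).
#' @return A `maxent_model` with the signed weight vector, bias, and
#'   training metadata (`iterations`, `objective`, `grad_norm`,
#'   `converged`).
#' @export
maxent_train <- function(pos, neg, config = maxent_config(), vocab = NULL) {
  Xp <- as_training_matrix(pos)
  Xn <- as_training_matrix(neg)
  if (!nrow(Xp) || !nrow(Xn)) {
    stop("both positive and negative sets must be non-empty", call. = FALSE)
  }
  if (ncol(Xp) != ncol(Xn)) {
    stop("positive and negative sets use different vocabularies",
         call. = FALSE)
  }
  X <- rbind(Xp, Xn)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xn)))
  V <- ncol(X)
  inv_var <- 1 / config$l2_variance
  Xt <- Matrix::t(X)

  nll <- function(theta) {
    eta <- theta[1L] + as.numeric(X %*% theta[-1L])
    val <- -sum(y * eta - log1pexp(eta)) +
      0.5 * inv_var * sum(theta[-1L]^2)
    if (!is.finite(val)) {
      stop("non-finite objective during maximum-entropy training ",
           "(check the regularization strength and feature scale)",
           call. = FALSE)
    }
    val
  }
  gr <- function(theta) {
    eta <- theta[1L] + as.numeric(X %*% theta[-1L])
    r <- stats::plogis(eta) - y
    c(sum(r), as.numeric(Xt %*% r) + inv_var * theta[-1L])
  }

  theta0 <- numeric(V + 1L)  # all parameters start at 0
  fit <- stats::optim(theta0, nll, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iter,
                                     factr = 10, pgtol = config$tol / 10))
  grad_norm <- sqrt(sum(gr(fit$par)^2))
  iterations <- fit$counts[["function"]]
  structure(list(
    bias = fit$par[1L],
    weights = fit$par[-1L],
    l2_variance = config$l2_variance,
    vocab = vocab,
    iterations = as.integer(iterations),
    objective = fit$value,
    grad_norm = grad_norm,
    converged = grad_norm < config$tol
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model: %d features, bias %.4f, ",
                     "objective %.4f, grad norm %.2e, %s>\n"),
              length(x$weights), x$bias, x$objective, x$grad_norm,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Positive-class posterior probability
#'
#' Features absent from the document (or unseen during training)
#' contribute nothing; an empty document scores `plogis(bias)`.
#'
#' @param m A `maxent_model`.
#' @param x A `feature_vector`, or a sparse matrix of documents (rows).
#' @return Probability (vector) in (0, 1).
#' @export
maxent_score <- function(m, x) {
  eta <- if (inherits(x, "feature_vector")) {
    m$bias + sum(m$weights[x$idx] * x$cnt)
  } else {
    m$bias + as.numeric(x %*% m$weights)
  }
  stats::plogis(eta)
}

#' Most influential classifier features
#'
#' Tokens ranked by signed weight.  With `report_filter = TRUE` (the
#' reporting convention for feature tables), stopwords and tokens of three
#' or fewer characters are removed before ranking; training itself keeps
#' all tokens of length >= 2.
#'
#' @param m A `maxent_model` carrying a vocabulary.
#' @param n How many features per direction.
#' @param report_filter Apply the reporting filter.
#' @param stopwords Stopword list used by the filter.
#' @return List with data frames `positive` and `negative`
#'   (`token`, `weight`), each at most `n` rows.
#' @export
top_features <- function(m, n = 5L, report_filter = TRUE,
                         stopwords = default_stopwords()) {
  if (is.null(m$vocab)) {
    stop("model carries no vocabulary; train with vocab = ", call. = FALSE)
  }
  tokens <- m$vocab$tokens
  w <- m$weights
  keep <- rep(TRUE, length(tokens))
  if (report_filter) {
    keep <- nchar(tokens) > 3L & !tokens %in% stopwords
  }
  tokens <- tokens[keep]; w <- w[keep]
  ord_pos <- order(-w, tokens)
  ord_neg <- order(w, tokens)
  n_pos <- min(n, sum(w > 0))
  n_neg <- min(n, sum(w < 0))
  list(
    positive = data.frame(token = tokens[ord_pos][seq_len(n_pos)],
                          weight = w[ord_pos][seq_len(n_pos)],
                          stringsAsFactors = FALSE),
    negative = data.frame(token = tokens[ord_neg][seq_len(n_neg)],
                          weight = w[ord_neg][seq_len(n_neg)],
                          stringsAsFactors = FALSE))
}

# Serialization ----------------------------------------------------------

maxent_model_to_list <- function(m) {
  nz <- which(m$weights != 0)
  list(
    format_version = 1L,
    bias = m$bias,
    weight_index = nz,
    weight_value = m$weights[nz],
    n_features = length(m$weights),
    l2_variance = m$l2_variance,
    vocab = if (!is.null(m$vocab)) m$vocab$tokens,
    iterations = m$iterations,
    objective = m$objective,
    grad_norm = m$grad_norm,
    converged = m$converged)
}

maxent_model_from_list <- function(l) {
  w <- numeric(l$n_features)
  w[as.integer(unlist(l$weight_index))] <- as.numeric(unlist(l$weight_value))
  vocab <- if (!is.null(l$vocab)) {
    structure(list(tokens = l$vocab, frozen = TRUE), class = "vocabulary")
  }
  structure(list(
    bias = l$bias, weights = w, l2_variance = l$l2_variance,
    vocab = vocab, iterations = l$iterations, objective = l$objective,
    grad_norm = l$grad_norm, converged = l$converged),
    class = "maxent_model")
}

#' Write a maximum-entropy model to versioned JSON
#' @param m A `maxent_model`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_maxent_model <- function(m, path) {
  # I(17) significant digits: doubles round-trip bit-identically
  jsonlite::write_json(maxent_model_to_list(m), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read a maximum-entropy model from JSON
#' @param path Path written by [write_maxent_model()].
#' @return A `maxent_model` whose scores are bit-identical to the
#'   serialized model's.
#' @export
read_maxent_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  maxent_model_from_list(l)
}
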