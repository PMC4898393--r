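#' Logistic segment-call classifier
#'
#' A segment call is classified as a true CNV by a logistic regression on
#' features of the call. The model is trained on known positives (progeny
#' calls validated by trio inheritance) and known false positives (calls
#' from a self-self hybridization of the reference sample against itself).
#'
#' `logistic_model()` builds a model object from named coefficients;
#' `published_model()` returns the fixed survey model
#'
#' \deqn{\mathrm{logit}(p) = -0.19 + 29.51\,\mathrm{absl2r}
#'   - 4.91\,\ln(\ln(\mathrm{length})) + 8.24\,\ln(\ln(\mathrm{datapoints}))}
#'
#' with acceptance threshold 0.95.
#'
#' @param coefficients named numeric vector; names from the term vocabulary
#'   (`"(Intercept)"`, `absl2r`, `del`, `length`, `ln_length`, `lnln_length`,
#'   `length_sq`, `datapoints`, `ln_datapoints`, `lnln_datapoints`,
#'   `datapoints_sq`, and `:`-joined interactions of those).
#' @param threshold acceptance threshold in (0, 1).
#' @return an object of class `LogisticModel`.
#' @export
logistic_model <- function(coefficients, threshold = 0.95) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(coefficients = coefficients, threshold = threshold),
            class = "LogisticModel")
}

#' @rdname logistic_model
#' @export
published_model <- function() {
  logistic_model(c("(Intercept)" = -0.19, absl2r = 29.51,
                   lnln_length = -4.91, lnln_datapoints = 8.24),
                 threshold = 0.95)
}

#' @export
print.LogisticModel <- function(x, ...) {
  cat("LogisticModel (threshold", x$threshold, ")\n")
  print(x$coefficients)
  invisible(x)
}

# Term vocabulary: map call features to model design columns. Interactions
# are named "a:b" and are plain products of the main-term columns.
.main_terms <- c("absl2r", "del", "length", "ln_length", "lnln_length",
                 "length_sq", "datapoints", "ln_datapoints",
                 "lnln_datapoints", "datapoints_sq")

.feature_frame <- function(calls) {
  len <- calls$length
  dp <- calls$datapoints
  data.frame(
    absl2r = calls$absl2r,
    del = as.numeric(calls$l2r < 0),
    length = len,
    ln_length = log(len),
    lnln_length = log(log(len)),
    length_sq = len^2,
    datapoints = dp,
    ln_datapoints = log(dp),
    lnln_datapoints = log(log(dp)),
    datapoints_sq = dp^2
  )
}

.design_column <- function(term, feats) {
  if (term == "(Intercept)") return(rep(1, nrow(feats)))
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  unknown <- setdiff(parts, names(feats))
  if (length(unknown)) stop("unknown model term(s): ", paste(unknown, collapse = ", "))
  Reduce(`*`, feats[parts])
}

.design_matrix <- function(terms, feats) {
  cols <- lapply(terms, .design_column, feats = feats)
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

#' Predict the probability a segment call is a true CNV
#'
#' Evaluates the logistic model on each call. The double-log features
#' `ln(ln(length))` and `ln(ln(datapoints))` are undefined for calls with
#' `length <= 1` or `datapoints <= 1`; in the default batch mode such calls
#' receive `p = 0` (auto-reject — downstream filters require at least three
#' probes anyway), while `strict = TRUE` raises an error instead.
#'
#' @param model a `LogisticModel`.
#' @param calls segment-call data.frame.
#' @param strict error (rather than auto-reject) on calls where the double
#'   log is undefined.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' m <- published_model()
#' sc <- segment_calls(animal = "A", chrom = "chr1", start = 0, stop = 28706,
#'                     first_probe = 1, last_probe = 9, l2r = 0.54,
#'                     datapoints = 9)
#' predict_p(m, sc)  # ~0.99998
#' @export
predict_p <- function(model, calls, strict = FALSE) {
  stopifnot(inherits(model, "LogisticModel"))
  undef <- calls$length <= 1 | calls$datapoints <= 1
  if (any(undef) && strict) {
    stop("double-log features undefined for calls with length <= 1 or ",
         "datapoints <= 1 (", sum(undef), " call(s))")
  }
  p <- numeric(nrow(calls))
  ok <- !undef
  if (any(ok)) {
    feats <- .feature_frame(calls[ok, , drop = FALSE])
    terms <- names(model$coefficients)
    X <- .design_matrix(terms, feats)
    eta <- drop(X %*% model$coefficients)
    p[ok] <- stats::plogis(eta)
  }
  p
}

#' Validate progeny segment calls against parent calls
#'
#' A progeny call is validated when at least one parent reports a call at an
#' identical genomic location — the same first and last probe index (hence
#' the same start and stop) on the same chromosome. Validated calls are
#' treated as true, inherited CNVs for model training.
#'
#' @param progeny_calls,sire_calls,dam_calls segment-call data.frames; all
#'   calls must share one probe grid.
#' @return the validated subset of `progeny_calls`.
#' @export
validate_trios <- function(progeny_calls, sire_calls, dam_calls) {
  key <- function(df) paste(df$chrom, df$first_probe, df$last_probe, sep = "|")
  parent_keys <- unique(c(key(sire_calls), key(dam_calls)))
  progeny_calls[key(progeny_calls) %in% parent_keys, , drop = FALSE]
}

#' Assemble a training set from validated and self-self calls
#'
#' Trio-validated progeny calls get outcome 1 (true CNV); self-self calls get
#' outcome 0 (false positive). Only autosomal calls are used; non-autosomal
#' rows are dropped with a message.
#'
#' @param validated_calls trio-validated segment calls.
#' @param selfself_calls self-self hybridization segment calls.
#' @param layout a `GenomeLayout` (defines the autosome set).
#' @return data.frame of calls with an `outcome` column (1/0).
#' @export
build_training_set <- function(validated_calls, selfself_calls, layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  keep_auto <- function(df, label) {
    drop <- !(df$chrom %in% layout$autosomes)
    if (any(drop)) {
      message("dropping ", sum(drop), " non-autosomal ", label, " call(s)")
    }
    df[!drop, , drop = FALSE]
  }
  v <- keep_auto(as.data.frame(validated_calls), "validated")
  s <- keep_auto(as.data.frame(selfself_calls), "self-self")
  if (nrow(v) == 0 || nrow(s) == 0) {
    stop("both outcome classes are required to train (validated: ", nrow(v),
         ", self-self: ", nrow(s), ")")
  }
  v$outcome <- 1
  s$outcome <- 0
  common <- intersect(names(v), names(s))
  rbind(v[common], s[common])
}

# Wald chi-square p-values for each non-intercept coefficient of a glm fit.
.wald_table <- function(fit) {
  s <- summary(fit)$coefficients
  s <- s[rownames(s) != "(Intercept)", , drop = FALSE]
  data.frame(term = rownames(s), chisq = s[, "z value"]^2,
             p = stats::pchisq(s[, "z value"]^2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# Ridge-penalized logistic IRLS, used as a fallback under perfect separation.
.ridge_logit <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0  # don't penalize intercept
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  beta
}

.fit_logit <- function(terms, records, feats) {
  X <- cbind(`(Intercept)` = 1, .design_matrix(terms, feats))
  df <- as.data.frame(X[, -1, drop = FALSE])
  names(df) <- terms
  df$.y <- records$outcome
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(sprintf("`%s`", terms), ".y"),
               family = stats::binomial(), data = df)
  )
  fit
}

#' Forward stepwise logistic regression over the call-feature vocabulary
#'
#' Builds the classifier by forward stepwise selection: a candidate term is
#' added if its Wald chi-square p-value is at most `enter_p` (0.3), and
#' retained only while its p-value in the growing model stays at most
#' `stay_p` (0.35). Candidate main effects are absl2r, the deletion
#' indicator, length, ln(length), ln(ln(length)), length squared, probe
#' count, ln(probes), ln(ln(probes)) and probes squared; two- and three-way
#' interactions are considered among main effects already in the model. Ties
#' on entry p are broken toward the larger Wald statistic. Selection is
#' deterministic given the record order.
#'
#' Perfect separation is flagged and the final coefficients are refit with a
#' light ridge penalty (with a warning).
#'
#' @param records training data.frame (calls plus `outcome`), e.g. from
#'   [build_training_set()].
#' @param enter_p,stay_p entry / stay significance levels.
#' @param candidate_terms main-effect vocabulary to search.
#' @param threshold acceptance threshold stored on the returned model.
#' @param interactions consider 2-/3-way interactions among selected main
#'   effects (`TRUE`, the default search) or main effects only.
#' @return a `LogisticModel` with a `terms` attribute listing selected terms.
#' @export
stepwise_fit <- function(records, enter_p = 0.3, stay_p = 0.35,
                         candidate_terms = .main_terms, threshold = 0.95,
                         interactions = TRUE) {
  if (length(unique(records$outcome)) < 2) {
    stop("outcome is constant; cannot fit a classifier")
  }
  feats <- .feature_frame(records)
  bad <- !vapply(feats, function(x) all(is.finite(x)), TRUE)
  if (any(bad)) {
    # length-1 / single-probe records make the double logs undefined
    stop("non-finite features (check length > 1 and datapoints > 1): ",
         paste(names(feats)[bad], collapse = ", "))
  }
  selected <- character()
  repeat {
    # candidate pool: unused main terms + 2/3-way products of selected mains
    mains_in <- if (interactions) intersect(selected, candidate_terms)
                else character()
    inter <- character()
    if (length(mains_in) >= 2) {
      inter <- c(inter, utils::combn(mains_in, 2, paste, collapse = ":"))
    }
    if (length(mains_in) >= 3) {
      inter <- c(inter, utils::combn(mains_in, 3, paste, collapse = ":"))
    }
    pool <- setdiff(c(candidate_terms, inter), selected)
    if (length(pool) == 0) break
    best <- NULL
    for (cand in pool) {
      trial <- c(selected, cand)
      fit <- try(.fit_logit(trial, records, feats), silent = TRUE)
      if (inherits(fit, "try-error")) next
      wt <- .wald_table(fit)
      row <- wt[wt$term == sprintf("`%s`", cand) | wt$term == cand, , drop = FALSE]
      if (nrow(row) == 0 || !is.finite(row$p[1])) next
      if (!fit$converged || fit$deviance < 1e-6) {
        # (near-)perfect separation deflates the Wald statistic
        # (Hauck-Donner); a separating term is maximally significant
        row$p[1] <- 0
        row$chisq[1] <- Inf
      }
      if (row$p[1] <= enter_p &&
          (is.null(best) || row$p[1] < best$p ||
           (row$p[1] == best$p && row$chisq[1] > best$chisq))) {
        best <- list(term = cand, p = row$p[1], chisq = row$chisq[1])
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best$term)
    # backward purge: drop terms whose stay p exceeds stay_p (skipped under
    # separation, where Wald p-values are uniformly deflated/inflated)
    repeat {
      fit <- .fit_logit(selected, records, feats)
      if (!fit$converged || fit$deviance < 1e-6) break
      wt <- .wald_table(fit)
      wt$term <- gsub("`", "", wt$term)
      worst <- wt[which.max(wt$p), , drop = FALSE]
      if (nrow(worst) == 1 && is.finite(worst$p) && worst$p > stay_p) {
        selected <- setdiff(selected, worst$term)
        if (length(selected) == 0) break
      } else break
    }
    if (length(selected) == 0) break
  }
  if (length(selected) == 0) {
    fit <- stats::glm(records$outcome ~ 1, family = stats::binomial())
    coefs <- c("(Intercept)" = unname(stats::coef(fit)[1]))
    model <- logistic_model(coefs, threshold)
    attr(model, "terms") <- character()
    return(model)
  }
  fit <- .fit_logit(selected, records, feats)
  coefs <- stats::coef(fit)
  names(coefs) <- gsub("`", "", names(coefs))
  separated <- !fit$converged || fit$deviance < 1e-6 ||
    any(abs(coefs[-1]) > 1e3)
  if (separated) {
    warning("(quasi-)perfect separation detected; refitting with a ridge penalty")
    X <- cbind(`(Intercept)` = 1, .design_matrix(selected, feats))
    coefs <- .ridge_logit(X, records$outcome)
    names(coefs) <- c("(Intercept)", selected)
  }
  model <- logistic_model(coefs, threshold)
  attr(model, "terms") <- selected
  attr(model, "separated") <- separated
  model
}

#' Leave-one-out crossvalidation of the classifier
#'
#' For each record in turn, the model coefficients are re-estimated from all
#' other records (keeping the already-selected term set fixed — term
#' selection is not repeated per fold) and the left-out record's probability
#' is predicted. Accuracy at a threshold t is the fraction of records whose
#' thresholded prediction (`p >= t`) matches the label.
#'
#' @param records training data.frame with `outcome`.
#' @param terms character vector of model terms (e.g. `attr(model, "terms")`).
#' @param thresholds probability thresholds to evaluate.
#' @param select_threshold the threshold reported as chosen (default 0.95).
#' @return list with `accuracy` (data.frame threshold/accuracy), `p`
#'   (per-record LOO probabilities) and `threshold` (the configured choice).
#' @export
loo_crossvalidate <- function(records,
                              terms,
                              thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9,
                                             0.95, 0.96, 0.97, 0.98, 0.99),
                              select_threshold = 0.95) {
  n <- nrow(records)
  if (n < 10 || length(unique(records$outcome)) < 2) {
    stop("need at least 10 records with both classes")
  }
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    if (length(unique(train$outcome)) < 2) {
      warning("fold ", i, " skipped: only one class remains")
      next
    }
    feats <- .feature_frame(train)
    if (length(terms) == 0) {
      p[i] <- mean(train$outcome)
      next
    }
    fit <- .fit_logit(terms, train, feats)
    coefs <- stats::coef(fit)
    names(coefs) <- gsub("`", "", names(coefs))
    if (!all(is.finite(coefs))) {
      X <- cbind(`(Intercept)` = 1, .design_matrix(terms, feats))
      coefs <- .ridge_logit(X, train$outcome)
      names(coefs) <- c("(Intercept)", terms)
    }
    m <- logistic_model(coefs, threshold = select_threshold)
    p[i] <- predict_p(m, records[i, , drop = FALSE])
  }
  ok <- !is.na(p)
  acc <- vapply(thresholds, function(t) {
    mean((p[ok] >= t) == (records$outcome[ok] == 1))
  }, 0)
  list(accuracy = data.frame(threshold = thresholds, accuracy = acc),
       p = p, threshold = select_threshold)
}
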