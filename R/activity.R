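#' Bin a numeric feature into indicator parameters
#'
#' A fixed bin width is applied over the range of values; the upper-most and
#' lower-most bins are collapsed with their neighbors while they hold fewer
#' than `sparsity_min` points. Each (non-missing) value maps to exactly one
#' indicator. A constant feature yields a single degenerate bin flagged for
#' exclusion from regression.
#'
#' @param values numeric vector (training values)
#' @param width bin width (> 0)
#' @param sparsity_min minimum edge-bin occupancy before merging inward
#' @return list: `edges` (breaks), `indicators` (0/1 matrix, one column per
#'   bin), `degenerate` (logical)
#' @export
bin_feature <- function(values, width, sparsity_min = 5L) {
  assert_that(width > 0, "bin width must be > 0")
  v <- values[!is.na(values)]
  if (length(v) == 0L) stopf("bin_feature: all values missing")
  rng <- range(v)
  if (diff(rng) == 0) {
    return(list(edges = c(rng[1], rng[1] + width), degenerate = TRUE,
                indicators = matrix(1, length(values), 1,
                                    dimnames = list(NULL, sprintf("bin_%g", rng[1])))))
  }
  nb <- max(1, ceiling(diff(rng) / width))
  edges <- rng[1] + width * 0:nb
  repeat {
    idx <- bin_index(v, edges)
    counts <- tabulate(idx, nbins = length(edges) - 1L)
    if (length(counts) > 1L && counts[1] < sparsity_min) {
      edges <- edges[-2]
    } else if (length(counts) > 1L && counts[length(counts)] < sparsity_min) {
      edges <- edges[-(length(edges) - 1L)]
    } else break
  }
  list(edges = edges, degenerate = FALSE,
       indicators = bin_apply(values, edges))
}

# bin index with [e_k, e_{k+1}) bins, last bin right-closed; out-of-range
# values clamp to the first/last bin (needed when applying training edges
# to new data)
bin_index <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(edges) - 1L)
}

# indicator matrix for stored edges; NA values give all-zero rows
bin_apply <- function(values, edges) {
  nb <- length(edges) - 1L
  m <- matrix(0, length(values), nb,
              dimnames = list(NULL, sprintf("bin_%g", edges[-length(edges)])))
  ok <- !is.na(values)
  if (any(ok)) m[cbind(which(ok), bin_index(values[ok], edges))] <- 1
  m
}

#' Fit a kernel position curve (activity vs distance to a TSS edge)
#'
#' Fits a radial-basis-function regressor of activity score on signed
#' distance, with hyperparameters C (inverse regularization) and gamma
#' (kernel bandwidth) selected by cross-validated grid search within the
#' training data. The fitted curve evaluated at a candidate's position is
#' then used as its transformed linear parameter. Implemented as RBF kernel
#' ridge regression (observations collapsed to unique integer positions
#' with weights), which exposes the same (C, gamma) hyperparameter surface
#' as support-vector regression and is deterministic given the seed.
#'
#' @param distance signed distances (bp)
#' @param activity activity scores
#' @param window valid position window, default -1500..1500 bp
#' @param cv_folds cross-validation folds for the grid search
#' @param seed RNG seed controlling fold assignment
#' @param C_grid,gamma_grid hyperparameter grids (log-spaced)
#' @param min_pairs minimum training pairs required inside the window
#' @return object of class `position_model`
#' @export
fit_position_svr <- function(distance, activity, window = c(-1500, 1500),
                             cv_folds = 3L, seed = 1L,
                             C_grid = 10^(-2:3), gamma_grid = 10^(-7:-2),
                             min_pairs = 200L) {
  keep <- !is.na(distance) & !is.na(activity) &
    distance >= window[1] & distance <= window[2]
  x <- distance[keep]; y <- activity[keep]
  if (length(x) < min_pairs)
    stopf("fit_position_svr: only %d training pairs inside window (need >= %d)",
          length(x), min_pairs)
  if (stats::sd(y) == 0) {
    warnf("fit_position_svr: all activities identical; returning flat model")
    return(structure(list(flat = TRUE, value = y[1], window = window),
                     class = "position_model"))
  }
  # collapse to unique positions: weighted mean response per position
  xu <- sort(unique(x))
  w <- as.numeric(table(factor(x, levels = xu)))
  yu <- as.numeric(tapply(y, factor(x, levels = xu), mean))
  ybar <- stats::weighted.mean(yu, w)
  yc <- yu - ybar

  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), length(xu))))
  best <- NULL; best_err <- Inf
  for (gamma in gamma_grid) {
    K <- exp(-gamma * outer(xu, xu, "-")^2)
    for (C in C_grid) {
      lambda <- 1 / C
      err <- 0
      for (f in seq_len(cv_folds)) {
        tr <- folds != f; te <- !tr
        if (!any(te) || sum(tr) < 2L) next
        a <- tryCatch(
          solve(K[tr, tr] + lambda * diag(1 / w[tr]), yc[tr]),
          error = function(e) NULL)
        if (is.null(a)) { err <- Inf; break }
        pred <- K[te, tr, drop = FALSE] %*% a
        err <- err + sum(w[te] * (yc[te] - pred)^2)
      }
      if (err < best_err) { best_err <- err; best <- list(C = C, gamma = gamma) }
    }
  }
  K <- exp(-best$gamma * outer(xu, xu, "-")^2)
  alpha <- solve(K + (1 / best$C) * diag(1 / w), yc)
  structure(list(flat = FALSE, x = xu, alpha = as.numeric(alpha),
                 gamma = best$gamma, C = best$C, ybar = ybar,
                 window = window),
            class = "position_model")
}

#' Predict a position curve at given distances
#' @param object `position_model`
#' @param positions signed distances (bp); clamped to the model window
#' @param ... unused
#' @return predicted activity contribution at each position
#' @export
predict.position_model <- function(object, positions, ...) {
  if (isTRUE(object$flat)) return(rep(object$value, length(positions)))
  p <- pmin(pmax(positions, object$window[1]), object$window[2])
  K <- exp(-object$gamma * outer(p, object$x, "-")^2)
  out <- as.numeric(K %*% object$alpha) + object$ybar
  out[is.na(positions)] <- NA_real_
  out
}

# feature category from an original roster column name
feature_category <- function(nm) {
  ifelse(grepl("^dist_", nm), "position",
  ifelse(grepl("^chromatin_", nm), "chromatin",
  ifelse(grepl("^(mfe|paired)_", nm), "folding", "sequence")))
}

# Linearize a feature matrix. With recipe = NULL (training), fits bin edges
# and position curves against `activity`; otherwise applies a stored recipe.
# Returns list(X = numeric matrix, recipe).
linearize_features <- function(features, kind, activity = NULL, recipe = NULL,
                               n_bins = 15L, sparsity_min = 5L,
                               position_window = c(-1500, 1500),
                               cv_folds = 3L, seed = 1L) {
  fitting <- is.null(recipe)
  if (fitting) {
    assert_that(!is.null(activity), "training linearization needs activity scores")
    recipe <- list()
  }
  cols <- list()
  for (nm in names(features)) {
    v <- features[[nm]]
    k <- kind[[nm]]
    cat <- feature_category(nm)
    if (k == "binary") {
      out <- matrix(ifelse(is.na(v), 0, v), ncol = 1,
                    dimnames = list(NULL, nm))
      if (fitting) recipe[[nm]] <- list(type = "binary", category = cat)
    } else if (k == "position") {
      if (fitting) {
        if (all(is.na(v))) {
          recipe[[nm]] <- list(type = "drop", category = cat)
          next
        }
        pm <- tryCatch(
          fit_position_svr(v, activity, window = position_window,
                           cv_folds = cv_folds, seed = seed),
          error = function(e) NULL)
        if (is.null(pm)) {
          # too few in-window pairs to support a curve (common for the
          # secondary-TSS distances): keep only the missingness indicator
          warnf("position feature '%s' has too few training pairs; using a presence indicator only", nm)
          recipe[[nm]] <- list(type = "position_missing_only", category = cat)
        } else {
          recipe[[nm]] <- list(type = "position", model = pm, category = cat)
        }
      }
      r <- recipe[[nm]]
      if (r$type == "drop") next
      if (r$type == "position_missing_only") {
        out <- matrix(as.numeric(is.na(v)), ncol = 1,
                      dimnames = list(NULL, paste0("svr_", nm, "_missing")))
        cols[[nm]] <- out
        next
      }
      pred <- predict(r$model, v)
      out <- cbind(ifelse(is.na(pred), 0, pred), as.numeric(is.na(v)))
      colnames(out) <- paste0("svr_", nm, c("", "_missing"))
    } else {  # numeric -> bins
      if (fitting) {
        if (all(is.na(v)) || diff(range(v, na.rm = TRUE)) == 0) {
          recipe[[nm]] <- list(type = "drop", category = cat)
          next
        }
        width <- diff(range(v, na.rm = TRUE)) / n_bins
        bf <- bin_feature(v, width, sparsity_min)
        recipe[[nm]] <- list(type = "bins", edges = bf$edges, category = cat,
                             has_missing = anyNA(v))
      }
      r <- recipe[[nm]]
      if (r$type == "drop") next
      out <- bin_apply(v, r$edges)
      colnames(out) <- paste0(nm, "_", colnames(out))
      if (isTRUE(r$has_missing))
        out <- cbind(out, matrix(as.numeric(is.na(v)), ncol = 1,
                                 dimnames = list(NULL, paste0(nm, "_missing"))))
    }
    cols[[nm]] <- out
  }
  X <- do.call(cbind, cols)
  # map each linearized column back to its source feature's category
  colcat <- unlist(lapply(names(cols), function(nm)
    rep(recipe[[nm]]$category, ncol(cols[[nm]]))))
  names(colcat) <- colnames(X)
  list(X = X, recipe = recipe, column_category = colcat)
}

#' Fit the elastic-net sgRNA activity model
#'
#' Splits genes (never individual sgRNAs) into training and held-out sets,
#' linearizes features on the training set only (position curves, bins,
#' binary passthrough), z-standardizes every linearized parameter with
#' training statistics, and fits elastic-net linear regression with the
#' l1/l2 mixing ratio and regularization strength chosen by cross-validated
#' grid search.
#'
#' @param features feature data.frame from [build_feature_matrix()] (with
#'   `kind` and `roster_hash` attributes)
#' @param activity data.frame with columns `sgrna` (matching feature
#'   rownames), `gene`, `activity`
#' @param train_fraction gene-wise training fraction (0.8 for CRISPRi-style
#'   5-fold splits, 0.67 for CRISPRa-style 3-fold)
#' @param seed RNG seed (split, CV folds)
#' @param alpha_grid candidate l1/l2 mixing ratios
#' @param nfolds elastic-net CV folds
#' @param position_window,cv_folds passed to the position-curve fits
#' @return object of class `activity_model`
#' @export
fit_activity_model <- function(features, activity, train_fraction = 0.8,
                               seed = 1L,
                               alpha_grid = c(0.1, 0.25, 0.5, 0.75, 0.9),
                               nfolds = 5L, position_window = c(-1500, 1500),
                               cv_folds = 3L) {
  kind <- attr(features, "kind")
  rh <- attr(features, "roster_hash") %||%
    fnv1a_hash(paste(names(features), kind, sep = ":"))
  idx <- match(activity$sgrna, rownames(features))
  assert_that(!anyNA(idx), "activity table contains sgRNAs absent from features")
  genes <- unique(activity$gene)
  train_genes <- with_seed(seed,
    sample(genes, size = max(1L, round(train_fraction * length(genes)))))
  test_genes <- setdiff(genes, train_genes)
  if (length(intersect(train_genes, test_genes)))
    stopf("test genes overlap train genes")
  tr <- activity$gene %in% train_genes
  f_tr <- features[idx[tr], , drop = FALSE]
  y_tr <- activity$activity[tr]

  lin <- linearize_features(f_tr, kind, activity = y_tr,
                            position_window = position_window,
                            cv_folds = cv_folds, seed = seed)
  X <- lin$X
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  keep <- sdev > 0
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")

  foldid <- with_seed(seed + 1L, sample(rep_len(seq_len(nfolds), nrow(Z))))
  best <- NULL; best_cvm <- Inf
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(Z, y_tr, alpha = a, foldid = foldid,
                            standardize = FALSE)
    m <- min(cv$cvm)
    if (m < best_cvm) { best_cvm <- m; best <- list(alpha = a, cv = cv) }
  }
  co <- as.numeric(stats::coef(best$cv, s = "lambda.min"))
  structure(list(
    recipe = lin$recipe,
    column_category = lin$column_category,
    mean = mu, sd = sdev, keep = keep,
    intercept = co[1],
    coefficients = stats::setNames(co[-1], colnames(Z)),
    alpha = best$alpha, lambda = best$cv$lambda.min,
    roster_hash = rh, roster = names(features),
    train_genes = sort(train_genes), test_genes = sort(test_genes),
    seed = seed), class = "activity_model")
}

# linearize + standardize a feature matrix under a fitted model
model_design_matrix <- function(model, features) {
  kind <- attr(features, "kind")
  rh <- attr(features, "roster_hash") %||%
    fnv1a_hash(paste(names(features), kind, sep = ":"))
  if (!identical(rh, model$roster_hash))
    stopf("feature roster does not match the model (hash %s vs %s)",
          rh, model$roster_hash)
  lin <- linearize_features(features, kind, recipe = model$recipe)
  X <- lin$X[, names(model$keep), drop = FALSE]
  keep <- model$keep
  sweep(sweep(X[, keep, drop = FALSE], 2, model$mean[keep]), 2,
        model$sd[keep], "/")
}

#' Predict sgRNA activity scores
#'
#' Pure function of (model, features): intercept + sum of coefficient times
#' z-transformed linearized parameter. Errors on a roster mismatch rather
#' than silently coercing.
#'
#' @param model `activity_model`
#' @param features feature data.frame with the model's roster
#' @return named numeric vector of predicted scores
#' @export
predict_activity <- function(model, features) {
  Z <- model_design_matrix(model, features)
  stats::setNames(as.numeric(model$intercept + Z %*% model$coefficients),
                  rownames(features))
}

#' Evaluate an activity model by ROC on held-out data
#'
#' Labels sgRNAs with empirical activity above `active_threshold` (0.75 by
#' default) as highly active and computes the ROC curve and AUC over the
#' full predicted-score ranking.
#'
#' @param model `activity_model`
#' @param features held-out feature matrix
#' @param activity held-out empirical activity scores (aligned to rows)
#' @param active_threshold activity score defining "highly active"
#' @return list: `auc`, `roc` (fpr/tpr), `predicted`
#' @export
evaluate_model <- function(model, features, activity, active_threshold = 0.75) {
  pred <- predict_activity(model, features)
  labels <- activity > active_threshold
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stopf("AUC undefined: held-out set contains a single class")
  rc <- roc_curve(pred, labels)
  list(auc = rc$auc, roc = rc, predicted = pred)
}

#' Per-category contribution to predicted score spread
#'
#' For each feature category (position, sequence, folding, chromatin), sums
#' each sgRNA's weighted (coefficient x z-parameter) terms within the
#' category and reports the 95th minus 5th percentile of those sums across
#' sgRNAs — the category's contribution to the spread of predicted scores.
#'
#' @param model `activity_model`
#' @param features feature matrix (typically the held-out set)
#' @return named numeric vector of contributions per category
#' @export
feature_category_contribution <- function(model, features) {
  Z <- model_design_matrix(model, features)
  contrib <- sweep(Z, 2, model$coefficients, "*")
  cats <- model$column_category[colnames(Z)]
  out <- vapply(sort(unique(cats)), function(cc) {
    s <- rowSums(contrib[, cats == cc, drop = FALSE])
    unname(diff(stats::quantile(s, c(0.05, 0.95))))
  }, numeric(1))
  out
}

#' Serialize / restore an activity model as versioned JSON
#'
#' @param model `activity_model`
#' @param path output JSON path
#' @export
write_activity_model <- function(model, path) {
  ser <- list(
    format_version = 1L,
    roster_hash = model$roster_hash, roster = model$roster,
    alpha = model$alpha, lambda = model$lambda,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    mean = as.list(model$mean), sd = as.list(model$sd),
    keep = as.list(model$keep),
    column_category = as.list(model$column_category),
    train_genes = model$train_genes, test_genes = model$test_genes,
    seed = model$seed,
    recipe = lapply(model$recipe, function(r) {
      if (r$type == "position" && !isTRUE(r$model$flat)) {
        list(type = r$type, category = r$category,
             x = r$model$x, alpha = r$model$alpha, gamma = r$model$gamma,
             C = r$model$C, ybar = r$model$ybar, window = r$model$window)
      } else if (r$type == "position") {
        list(type = r$type, category = r$category, flat = TRUE,
             value = r$model$value, window = r$model$window)
      } else r
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_activity_model
#' @export
read_activity_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  recipe <- lapply(ser$recipe, function(r) {
    if (r$type == "position") {
      pm <- if (isTRUE(r$flat)) {
        structure(list(flat = TRUE, value = r$value, window = r$window),
                  class = "position_model")
      } else {
        structure(list(flat = FALSE, x = r$x, alpha = r$alpha,
                       gamma = r$gamma, C = r$C, ybar = r$ybar,
                       window = r$window), class = "position_model")
      }
      list(type = "position", model = pm, category = r$category)
    } else r
  })
  structure(list(
    recipe = recipe,
    column_category = unlist(ser$column_category),
    mean = unlist(ser$mean), sd = unlist(ser$sd), keep = unlist(ser$keep),
    intercept = ser$intercept,
    coefficients = unlist(ser$coefficients),
    alpha = ser$alpha, lambda = ser$lambda,
    roster_hash = ser$roster_hash, roster = ser$roster,
    train_genes = ser$train_genes, test_genes = ser$test_genes,
    seed = ser$seed), class = "activity_model")
}
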