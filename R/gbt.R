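# Reference gradient boosted trees: Friedman-style stagewise boosting with
# CART base learners grown by greedy squared-error split search. Every split
# candidate includes a learned default direction for missing values, so the
# model consumes incomplete registry features directly. An adapter to the
# xgboost library (predictors.R) satisfies the same contract for
# production-scale runs; this implementation is the transparent reference.

#' Loss family for boosting
#'
#' Bundles the loss value, its negative gradient, the optimal constant
#' initializer, the terminal-node estimate rule and the mean link.
#' For squared loss the negative gradient is `y - f` and the leaf estimate is
#' the exact argmin (the leaf mean of residuals). For logistic loss on the
#' raw score the negative gradient is `y - sigmoid(f)` and the leaf estimate
#' is the one-step Newton approximation `sum(y - p) / sum(p (1 - p))`.
#'
#' @param name `"squared"` or `"logistic"`.
#' @return a `loss_family` object.
#' @export
loss_family <- function(name = c("squared", "logistic")) {
  name <- match.arg(name)
  if (name == "squared") {
    fam <- list(
      name = "squared",
      value = function(y, f) (y - f)^2,
      ngrad = function(y, f) y - f,
      init = function(y) mean(y),
      leaf = function(y, f) mean(y - f),
      link = identity
    )
  } else {
    fam <- list(
      name = "logistic",
      # -[y log p + (1-y) log(1-p)] on the raw score, numerically stable
      value = function(y, f) log1p(exp(-abs(f))) + pmax(f, 0) - y * f,
      ngrad = function(y, f) y - stats::plogis(f),
      init = function(y) {
        p <- min(max(mean(y), 1e-12), 1 - 1e-12)
        stats::qlogis(p)
      },
      leaf = function(y, f) {
        p <- stats::plogis(f)
        sum(y - p) / max(sum(p * (1 - p)), 1e-12)
      },
      link = stats::plogis
    )
  }
  structure(fam, class = "loss_family")
}

#' Boosting configuration
#'
#' Defaults follow the unoptimized booster variant (`learning_rate = 0.3`,
#' `n_rounds = 50`); the optimized variant uses `learning_rate = 0.1` with
#' `early_stopping = TRUE`, which selects the number of rounds by k-fold
#' cross-validated loss with a patience rule.
#'
#' @param learning_rate shrinkage alpha > 0 applied to every stage.
#' @param n_rounds number of trees T (>= 0); under early stopping, the cap.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf_size minimum examples per leaf.
#' @param loss `"squared"` or `"logistic"` (or a [loss_family()]).
#' @param early_stopping select T by cross-validation.
#' @param cv_folds folds for early stopping.
#' @param patience stop scanning after this many rounds without CV
#'   improvement.
#' @param seed integer seed (fold assignment).
#' @return a `gbt_config` object.
#' @export
gbt_config <- function(learning_rate = 0.3, n_rounds = 50L, max_depth = 6L,
                       min_leaf_size = 20L, loss = "squared",
                       early_stopping = FALSE, cv_folds = 5L,
                       patience = 10L, seed = 1L) {
  stopifnot(learning_rate > 0, n_rounds >= 0, max_depth >= 1, min_leaf_size >= 1)
  if (!inherits(loss, "loss_family")) loss <- loss_family(loss)
  structure(list(learning_rate = learning_rate, n_rounds = as.integer(n_rounds),
                 max_depth = as.integer(max_depth),
                 min_leaf_size = as.integer(min_leaf_size), loss = loss,
                 early_stopping = isTRUE(early_stopping),
                 cv_folds = as.integer(cv_folds), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "gbt_config")
}

# Best (score, split) for one numeric feature at a node. Score is the
# sum over children of (sum of targets)^2 / n — maximizing it maximizes the
# squared-error reduction of a constant-leaf split. Candidate thresholds are
# midpoints between consecutive distinct observed values; when missing values
# are present an extra candidate isolates them (threshold +Inf, missing
# right) so missingness itself can act as the splitting criterion.
best_split_numeric <- function(v, t, min_leaf) {
  miss <- is.na(v)
  n_miss <- sum(miss)
  s_miss <- sum(t[miss])
  vo <- v[!miss]; to <- t[!miss]
  n_obs <- length(vo)
  best <- NULL
  if (n_obs >= 2L) {
    o <- order(vo)
    sv <- vo[o]
    cs <- cumsum(to[o])
    tot <- cs[n_obs] + s_miss
    n_tot <- n_obs + n_miss
    i <- seq_len(n_obs - 1L)
    ok <- sv[i] < sv[i + 1L]
    if (any(ok)) {
      i <- i[ok]
      thr <- (sv[i] + sv[i + 1L]) / 2
      csl <- cs[i]
      for (dir in c("left", "right")) {
        nl <- i + if (dir == "left") n_miss else 0L
        sl <- csl + if (dir == "left") s_miss else 0
        nr <- n_tot - nl
        sr <- tot - sl
        valid <- nl >= min_leaf & nr >= min_leaf
        if (n_miss == 0L && dir == "right") next  # identical to "left"
        if (any(valid)) {
          sc <- ifelse(valid, sl^2 / nl + sr^2 / nr, -Inf)
          j <- which.max(sc)
          if (is.null(best) || sc[j] > best$score) {
            best <- list(score = sc[j], threshold = thr[j], missing_dir = dir)
          }
        }
      }
    }
  }
  # missing-only split: all observed left, missing right
  if (n_miss >= min_leaf && n_obs >= min_leaf && n_obs >= 1L) {
    so <- sum(to)
    sc <- so^2 / n_obs + s_miss^2 / n_miss
    if (is.null(best) || sc > best$score) {
      best <- list(score = sc, threshold = Inf, missing_dir = "right")
    }
  }
  best
}

# one-vs-rest split search for a factor feature
best_split_factor <- function(v, t, min_leaf) {
  miss <- is.na(v)
  n_miss <- sum(miss)
  s_miss <- sum(t[miss])
  n_tot <- length(t)
  tot <- sum(t)
  lev_n <- tapply(!miss, v, sum)
  lev_s <- tapply(ifelse(miss, 0, t), v, sum)
  best <- NULL
  for (l in levels(v)) {
    nl0 <- lev_n[[l]] %||% 0L
    if (is.na(nl0) || nl0 == 0L) next
    sl0 <- lev_s[[l]]
    for (dir in c("left", "right")) {
      if (n_miss == 0L && dir == "right") next
      nl <- nl0 + if (dir == "left") n_miss else 0L
      sl <- sl0 + if (dir == "left") s_miss else 0
      nr <- n_tot - nl
      sr <- tot - sl
      if (nl < min_leaf || nr < min_leaf) next
      sc <- sl^2 / nl + sr^2 / nr
      if (is.null(best) || sc > best$score) {
        best <- list(score = sc, level = l, missing_dir = dir)
      }
    }
  }
  best
}

route_left <- function(v, split) {
  if (split$type == "numeric") {
    lt <- !is.na(v) & v < split$threshold
  } else {
    lt <- !is.na(v) & v == split$level
  }
  if (split$missing_dir == "left") lt | is.na(v) else lt
}

#' Fit a regression tree (CART) with missing-direction splits
#'
#' Greedy depth-first growth. Each split maximizes the squared-error
#' reduction over all (feature, threshold or level, missing-direction)
#' candidates; continuous candidates are midpoints between consecutive sorted
#' distinct values, categorical candidates are one-vs-rest level splits. Ties
#' in gain are broken by lowest feature index, then lowest threshold. Growth
#' stops at `max_depth`, at `min_leaf_size`, or when no split improves the
#' fit. Leaves carry the mean target (replaced by the loss family's
#' terminal-node estimate inside boosting).
#'
#' @param X data.frame of features (numeric or factor, NAs allowed).
#' @param target numeric response vector.
#' @param max_depth,min_leaf_size stopping rules.
#' @return a `cart_tree`: flat list of nodes (preorder), node 1 the root.
#' @export
fit_cart <- function(X, target, max_depth = 6L, min_leaf_size = 1L) {
  if (length(target) == 0L || nrow(X) == 0L) stop("empty input")
  stopifnot(nrow(X) == length(target), is.numeric(target))
  nodes <- list()
  feat_names <- names(X)

  grow <- function(idx, depth) {
    t <- target[idx]
    n <- length(t)
    me <- length(nodes) + 1L
    leaf_value <- mean(t)
    make_leaf <- function() {
      nodes[[me]] <<- list(leaf = TRUE, value = leaf_value, n = n)
      me
    }
    if (depth >= max_depth || n < 2L * min_leaf_size ||
        max(t) - min(t) < 1e-15) return(make_leaf())

    parent_score <- sum(t)^2 / n
    best <- NULL
    for (j in seq_along(feat_names)) {
      v <- X[[j]][idx]
      if (all(is.na(v))) next
      cand <- if (is.factor(v)) best_split_factor(v, t, min_leaf_size)
              else best_split_numeric(v, t, min_leaf_size)
      if (!is.null(cand) && cand$score > parent_score + 1e-10 &&
          (is.null(best) || cand$score > best$score + 1e-12)) {
        best <- cand
        best$feature <- feat_names[j]
        best$type <- if (is.factor(v)) "factor" else "numeric"
      }
    }
    if (is.null(best)) return(make_leaf())

    nodes[[me]] <<- list(leaf = FALSE, feature = best$feature, type = best$type,
                         threshold = best$threshold %||% NA_real_,
                         level = best$level %||% NA_character_,
                         missing_dir = best$missing_dir, n = n)
    lt <- route_left(X[[best$feature]][idx], best)
    nodes[[me]]$left <<- grow(idx[lt], depth + 1L)
    nodes[[me]]$right <<- grow(idx[!lt], depth + 1L)
    me
  }
  grow(seq_along(target), 0L)
  structure(nodes, class = "cart_tree")
}

# leaf node index per row
tree_leaf_ids <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  descend <- function(node_id, idx) {
    node <- tree[[node_id]]
    if (isTRUE(node$leaf)) {
      out[idx] <<- node_id
      return(invisible())
    }
    lt <- route_left(X[[node$feature]][idx], node)
    if (any(lt)) descend(node$left, idx[lt])
    if (any(!lt)) descend(node$right, idx[!lt])
  }
  if (n > 0L) descend(1L, seq_len(n))
  out
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  ids <- tree_leaf_ids(object, newdata)
  vapply(ids, function(i) object[[i]]$value, numeric(1))
}

#' Fit a gradient boosted trees model (reference implementation)
#'
#' Starts from the loss family's optimal constant, then for each round fits a
#' regression tree to the negative gradient at the current fit, replaces its
#' leaf values with the loss family's terminal-node estimates, and adds the
#' tree scaled by the learning rate. With `early_stopping = TRUE` the number
#' of rounds is first selected by [select_rounds_by_cv()] and the model is
#' refitted on the full data.
#'
#' @param X data.frame of features (numeric/factor, NAs handled natively).
#' @param y response: `{0,1}` for logistic loss, real for squared.
#' @param config a [gbt_config()].
#' @return a `gbt_model` with fields `f0`, `trees`, `config`,
#'   `train_loss` (mean training loss after each round).
#' @export
boost <- function(X, y, config = gbt_config()) {
  stopifnot(inherits(config, "gbt_config"), nrow(X) == length(y))
  loss <- config$loss
  if (loss$name == "logistic" && !is_binary(y))
    stop("logistic loss requires binary {0,1} labels")

  if (config$early_stopping) {
    t_star <- select_rounds_by_cv(X, y, config)
    config$early_stopping <- FALSE
    config$n_rounds <- t_star
    return(boost(X, y, config))
  }

  f0 <- loss$init(y)
  f <- rep(f0, length(y))
  trees <- vector("list", config$n_rounds)
  train_loss <- numeric(config$n_rounds)
  for (t in seq_len(config$n_rounds)) {
    r <- loss$ngrad(y, f)
    tree <- fit_cart(X, r, config$max_depth, config$min_leaf_size)
    ids <- tree_leaf_ids(tree, X)
    for (leaf_id in unique(ids)) {
      rows <- ids == leaf_id
      tree[[leaf_id]]$value <- loss$leaf(y[rows], f[rows])
    }
    contrib <- vapply(ids, function(i) tree[[i]]$value, numeric(1))
    f <- f + config$learning_rate * contrib
    trees[[t]] <- tree
    train_loss[t] <- mean(loss$value(y, f))
  }
  structure(list(f0 = f0, trees = trees, config = config,
                 feature_names = names(X), train_loss = train_loss),
            class = "gbt_model")
}

#' Predict from a reference boosted-trees model
#'
#' @param object a `gbt_model`.
#' @param newdata data.frame with the training feature columns.
#' @param type `"response"` (mean link applied: probability under logistic
#'   loss) or `"score"` (raw additive score).
#' @param n_trees optionally truncate the ensemble to the first `n_trees`
#'   stages.
#' @param ... unused.
#' @export
predict.gbt_model <- function(object, newdata, type = c("response", "score"),
                              n_trees = NULL, ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks feature column(s): ", paste(missing_cols, collapse = ", "))
  f <- rep(object$f0, nrow(newdata))
  use <- object$trees
  if (!is.null(n_trees)) use <- use[seq_len(min(n_trees, length(use)))]
  for (tree in use) {
    f <- f + object$config$learning_rate * predict(tree, newdata)
  }
  if (type == "response") object$config$loss$link(f) else f
}

#' Select the best boosting round from a CV-loss sequence
#'
#' Scans mean held-out losses per round and returns the argmin, stopping the
#' scan once `patience` rounds pass without improvement. Round 0 (the
#' constant model) is included as a candidate: a return value of 0 means no
#' round improved on the constant.
#'
#' @param cv_loss numeric: mean held-out loss after round 1, 2, ...
#' @param loss0 held-out loss of the constant model (round 0); defaults to
#'   `Inf`, i.e. round 0 not considered.
#' @param patience scan patience.
#' @return best round (integer).
#' @export
best_round <- function(cv_loss, loss0 = Inf, patience = 10L) {
  best_t <- 0L
  best_v <- loss0
  for (t in seq_along(cv_loss)) {
    if (cv_loss[t] < best_v) {
      best_v <- cv_loss[t]
      best_t <- t
    } else if (t - best_t >= patience) break
  }
  best_t
}

#' Choose the number of boosting rounds by k-fold cross-validation
#'
#' Respondents are partitioned into `cv_folds` seeded folds; fold models grow
#' in lockstep one round at a time while the mean held-out loss (the training
#' loss family's own value) is tracked. Growth stops `patience` rounds past
#' the running minimum or at `n_rounds`, and the argmin round is returned.
#'
#' @param X,y training data.
#' @param config a [gbt_config()] with `early_stopping = TRUE`.
#' @return best number of rounds `T*` (may be 0).
#' @export
select_rounds_by_cv <- function(X, y, config) {
  k <- config$cv_folds
  if (k < 2L) stop("cv_folds must be >= 2")
  n <- length(y)
  if (n < k) stop("fewer rows than folds")
  loss <- config$loss
  set.seed(derive_seed(config$seed, "cv"))
  fold <- sample(rep(seq_len(k), length.out = n))

  state <- lapply(seq_len(k), function(i) {
    tr <- fold != i
    f0 <- loss$init(y[tr])
    list(tr = tr, f_tr = rep(f0, sum(tr)), f_te = rep(f0, sum(!tr)))
  })
  loss0 <- sum(vapply(state, function(s)
    sum(loss$value(y[!s$tr], s$f_te)), numeric(1))) / n

  cv_loss <- numeric(0)
  best_t <- 0L
  best_v <- loss0
  for (t in seq_len(config$n_rounds)) {
    val <- 0
    for (i in seq_len(k)) {
      s <- state[[i]]
      ytr <- y[s$tr]
      r <- loss$ngrad(ytr, s$f_tr)
      tree <- fit_cart(X[s$tr, , drop = FALSE], r, config$max_depth,
                       config$min_leaf_size)
      ids <- tree_leaf_ids(tree, X[s$tr, , drop = FALSE])
      for (leaf_id in unique(ids)) {
        rows <- ids == leaf_id
        tree[[leaf_id]]$value <- loss$leaf(ytr[rows], s$f_tr[rows])
      }
      contrib_tr <- vapply(ids, function(j) tree[[j]]$value, numeric(1))
      s$f_tr <- s$f_tr + config$learning_rate * contrib_tr
      s$f_te <- s$f_te + config$learning_rate *
        predict(tree, X[!s$tr, , drop = FALSE])
      state[[i]] <- s
      val <- val + sum(loss$value(y[!s$tr], s$f_te))
    }
    cv_loss[t] <- val / n
    if (cv_loss[t] < best_v) {
      best_v <- cv_loss[t]
      best_t <- t
    } else if (t - best_t >= config$patience) break
  }
  best_t
}

#' Serialize a reference model to JSON text
#'
#' Stores the constant, loss name, learning rate, feature schema and each
#' tree as its preorder node list at full floating-point precision; the
#' round trip through [gbt_load()] reproduces predictions bit-exactly.
#'
#' @param model a `gbt_model`.
#' @param path file path to write to.
#' @export
gbt_save <- function(model, path) {
  # doubles stored as %.17g strings: IEEE-754 round-trip exactness, which
  # JSON number serialization does not guarantee
  num <- function(v) sprintf("%.17g", v)
  obj <- list(
    format = "saeboost-gbt-1",
    f0 = num(model$f0),
    loss = model$config$loss$name,
    learning_rate = num(model$config$learning_rate),
    feature_names = model$feature_names,
    trees = lapply(model$trees, function(tree) {
      lapply(tree, function(nd) {
        if (isTRUE(nd$leaf)) list(leaf = TRUE, value = num(nd$value))
        else list(leaf = FALSE, feature = nd$feature, type = nd$type,
                  threshold = num(nd$threshold), level = nd$level,
                  missing_dir = nd$missing_dir, left = nd$left, right = nd$right)
      })
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a serialized reference model
#'
#' @param path file written by [gbt_save()].
#' @return a `gbt_model`.
#' @export
gbt_load <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "saeboost-gbt-1")) stop("unrecognized model format")
  as_num <- function(s) suppressWarnings(as.numeric(s))
  trees <- lapply(obj$trees, function(tree) {
    structure(lapply(tree, function(nd) {
      if (isTRUE(nd$leaf)) list(leaf = TRUE, value = as_num(nd$value))
      else list(leaf = FALSE, feature = nd$feature, type = nd$type,
                threshold = as_num(nd$threshold),
                level = if (is.null(nd$level)) NA_character_ else nd$level,
                missing_dir = nd$missing_dir,
                left = as.integer(nd$left), right = as.integer(nd$right))
    }), class = "cart_tree")
  })
  config <- gbt_config(learning_rate = as_num(obj$learning_rate),
                       n_rounds = length(trees), loss = obj$loss)
  structure(list(f0 = as_num(obj$f0), trees = trees, config = config,
                 feature_names = unlist(obj$feature_names),
                 train_loss = numeric(0)),
            class = "gbt_model")
}
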