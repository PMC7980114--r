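#' Train the feeling-of-health classifier
#'
#' Binary good/bad classifier over well-being records, with held-out
#' accuracy estimated on a stratified 80/20 split. The model also stores the
#' training range of every feature, used later to express modification
#' volumes on a unit-free scale.
#'
#' @param records Data frame of numeric features plus a `label` column with
#'   values `"good"`/`"bad"` (both must be present).
#' @param algorithm Currently `"random_forest"`.
#' @param seed Integer seed.
#' @param num_trees Trees (default 500).
#' @param holdout_frac Held-out fraction for the accuracy estimate
#'   (default 0.2).
#' @return A `health_model` with elements `fit`, `feature_names`,
#'   `accuracy` (percent, held-out), `ranges` (per-feature training range).
#' @export
train_health_model <- function(records, algorithm = "random_forest",
                               seed = 1L, num_trees = 500L,
                               holdout_frac = 0.2) {
  algorithm <- match.arg(algorithm, "random_forest")
  labs <- factor(records$label, levels = c("bad", "good"))
  if (length(unique(records$label)) < 2L) {
    stop("train_health_model: both labels must be present", call. = FALSE)
  }
  cols <- setdiff(names(records), c("label", "subject_id"))
  x <- records[, cols, drop = FALSE]
  set.seed(seed)
  test_idx <- unlist(lapply(levels(labs), function(l) {
    i <- which(labs == l)
    sample(i, max(1L, round(holdout_frac * length(i))))
  }))
  # probability forests with a fixed 0.5 decision rule: majority-vote
  # classification forests break exact vote ties randomly at predict time,
  # which would make admissibility checks non-deterministic
  fit_ho <- ranger::ranger(x = x[-test_idx, , drop = FALSE],
                           y = labs[-test_idx], num.trees = num_trees,
                           probability = TRUE, seed = seed, num.threads = 1L)
  pr_ho <- stats::predict(fit_ho, data = x[test_idx, , drop = FALSE],
                          num.threads = 1L)$predictions
  pred_ho <- ifelse(pr_ho[, "good"] > 0.5, "good", "bad")
  acc <- 100 * mean(pred_ho == labs[test_idx])
  fit <- ranger::ranger(x = x, y = labs, num.trees = num_trees,
                        probability = TRUE, seed = seed, num.threads = 1L)
  ranges <- vapply(x, function(v) diff(range(v)), numeric(1))
  structure(list(fit = fit, feature_names = cols, accuracy = acc,
                 ranges = ranges, seed = seed, n = nrow(records)),
            class = "health_model")
}

#' @export
print.health_model <- function(x, ...) {
  cat(sprintf("<health_model> random forest, %d records, held-out accuracy %.1f%%\n",
              x$n, x$accuracy))
  invisible(x)
}

#' Predict feeling of health
#'
#' @param object A `health_model`.
#' @param newdata Data frame with the model's feature columns.
#' @param ... Unused.
#' @return Character vector of `"good"`/`"bad"` (predicted good when the
#'   forest's class probability exceeds 0.5; an exact tie counts as bad).
#' @export
predict.health_model <- function(object, newdata, ...) {
  pr <- stats::predict(
    object$fit, data = newdata[, object$feature_names, drop = FALSE],
    num.threads = 1L)$predictions
  unname(ifelse(pr[, "good"] > 0.5, "good", "bad"))
}

#' Partition features into modifiable, correlated and uncorrelated
#'
#' A non-modifiable feature is declared correlated when the absolute Pearson
#' correlation with some modifiable feature reaches the threshold;
#' otherwise it is uncorrelated. Constant features have undefined
#' correlation and are assigned uncorrelated with a warning.
#'
#' @param records Well-being record data frame.
#' @param modifiable_names Names of the directly modifiable features (must
#'   be a subset of the schema).
#' @param threshold Absolute-correlation threshold in (0, 1), default 0.3.
#' @return A `feature_partition` with `modifiable`, `correlated`,
#'   `uncorrelated` name vectors, the `threshold`, and a `cor_matrix`
#'   (non-modifiable x modifiable).
#' @export
partition_features <- function(records, modifiable_names, threshold = 0.3) {
  cols <- setdiff(names(records), c("label", "subject_id"))
  if (!all(modifiable_names %in% cols)) {
    stop("partition_features: modifiable names outside schema", call. = FALSE)
  }
  if (!(threshold > 0 && threshold < 1)) {
    stop("partition_features: threshold must be in (0,1)", call. = FALSE)
  }
  other <- setdiff(cols, modifiable_names)
  cm <- matrix(NA_real_, length(other), length(modifiable_names),
               dimnames = list(other, modifiable_names))
  correlated <- character(0)
  uncorrelated <- character(0)
  for (f in other) {
    if (stats::sd(records[[f]]) <= 0) {
      warning("partition_features: constant feature '", f,
              "' assigned uncorrelated")
      uncorrelated <- c(uncorrelated, f)
      next
    }
    r <- vapply(modifiable_names, function(m) {
      if (stats::sd(records[[m]]) <= 0) 0 else
        stats::cor(records[[f]], records[[m]])
    }, numeric(1))
    cm[f, ] <- r
    if (max(abs(r)) >= threshold) correlated <- c(correlated, f)
    else uncorrelated <- c(uncorrelated, f)
  }
  structure(list(modifiable = modifiable_names, correlated = correlated,
                 uncorrelated = uncorrelated, threshold = threshold,
                 cor_matrix = cm, models = NULL),
            class = "feature_partition")
}

#' @export
print.feature_partition <- function(x, ...) {
  cat("<feature_partition>\n")
  cat("  modifiable:  ", paste(x$modifiable, collapse = ", "), "\n")
  cat("  correlated:  ", paste(x$correlated, collapse = ", "), "\n")
  cat("  uncorrelated:", paste(x$uncorrelated, collapse = ", "), "\n")
  invisible(x)
}

#' Fit linear propagation models for the correlated features
#'
#' Ordinary least squares of each correlated feature on all modifiable
#' features. A rank-deficient design is fit through the Moore-Penrose
#' pseudoinverse and flagged with a warning.
#'
#' @param records Well-being record data frame.
#' @param partition A `feature_partition`.
#' @return The partition with `models`: per correlated feature a list with
#'   `intercept`, `coefficients` (named over modifiable features) and
#'   `r_squared`.
#' @export
fit_correlated_models <- function(records, partition) {
  X <- as.matrix(records[, partition$modifiable, drop = FALSE])
  if (nrow(X) < length(partition$modifiable) + 2L) {
    stop("fit_correlated_models: too few records", call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  rank_def <- qr(Xd)$rank < ncol(Xd)
  if (rank_def) {
    warning("fit_correlated_models: rank-deficient design; using pseudoinverse")
  }
  models <- lapply(partition$correlated, function(f) {
    y <- records[[f]]
    beta <- if (rank_def) {
      as.numeric(MASS::ginv(Xd) %*% y)
    } else {
      as.numeric(qr.solve(Xd, y))
    }
    yhat <- as.numeric(Xd %*% beta)
    ss_res <- sum((y - yhat)^2)
    ss_tot <- sum((y - mean(y))^2)
    list(intercept = beta[1L],
         coefficients = stats::setNames(beta[-1L], partition$modifiable),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         rank_deficient = rank_def)
  })
  names(models) <- partition$correlated
  partition$models <- models
  partition
}

#' Propagate a modification through the feature partition
#'
#' Applies deltas to the modifiable features and updates every correlated
#' feature residual-preservingly: the correlated feature moves by the
#' difference between its linear-model prediction at the modified and the
#' original modifiable values, so a zero modification is exactly the
#' identity. Uncorrelated features are untouched.
#'
#' @param record One-row data frame (or named list) of feature values.
#' @param deltas Named numeric vector, nonzero only on modifiable names.
#' @param partition A `feature_partition` with fitted models.
#' @return The candidate record (one-row data frame).
#' @export
propagate <- function(record, deltas, partition) {
  record <- as.data.frame(record)
  nz <- names(deltas)[deltas != 0]
  if (!all(nz %in% partition$modifiable)) {
    stop("propagate: delta on non-modifiable feature", call. = FALSE)
  }
  if (length(partition$correlated) > 0L && is.null(partition$models)) {
    stop("propagate: partition has no fitted models", call. = FALSE)
  }
  out <- record
  d <- stats::setNames(rep(0, length(partition$modifiable)),
                       partition$modifiable)
  d[names(deltas)[names(deltas) %in% partition$modifiable]] <-
    deltas[names(deltas) %in% partition$modifiable]
  for (m in partition$modifiable) out[[m]] <- record[[m]] + d[[m]]
  for (f in partition$correlated) {
    coefs <- partition$models[[f]]$coefficients
    out[[f]] <- record[[f]] + sum(coefs * d[names(coefs)])
  }
  out
}

#' Modification objectives: volume and number of changed features
#'
#' The volume of a modification is the sum over features of the absolute
#' delta normalized by the feature's training-data range (unit-free);
#' `n_changed` counts the nonzero deltas.
#'
#' @param deltas Named numeric vector of feature deltas.
#' @param ranges Named numeric vector of training ranges (> 0) for the
#'   delta features.
#' @return Numeric vector `c(volume, n_changed)`.
#' @export
objectives <- function(deltas, ranges) {
  r <- ranges[names(deltas)]
  if (any(!is.finite(r) | r <= 0)) {
    stop("objectives: ranges must be positive for all delta features",
         call. = FALSE)
  }
  c(volume = sum(abs(deltas) / r), n_changed = sum(deltas != 0))
}

#' Fast non-dominated sort with crowding distance
#'
#' Partitions objective points into Pareto fronts under minimization of
#' both objectives, and computes the crowding distance within each front.
#'
#' @param points Numeric matrix, one row per point, columns = objectives.
#' @return List with `rank` (front index per point, 1 = non-dominated) and
#'   `crowding` (crowding distance per point, `Inf` at front extremes).
#' @export
nondominated_sort <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(list(rank = integer(0), crowding = numeric(0)))
  # vectorized dominance matrix: dom[i, j] is TRUE when i dominates j
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (m in seq_len(ncol(points))) {
    cm <- points[, m]
    le <- le & outer(cm, cm, `<=`)
    lt <- lt | outer(cm, cm, `<`)
  }
  dom <- le & lt
  dom_count <- colSums(dom)
  dom_set <- lapply(seq_len(n), function(i) which(dom[i, ]))
  rank <- integer(n)
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front) > 0L) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dom_set[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- unique(nxt)
    r <- r + 1L
  }
  crowding <- numeric(n)
  for (fr in unique(rank)) {
    idx <- which(rank == fr)
    if (length(idx) <= 2L) {
      crowding[idx] <- Inf
      next
    }
    cd <- numeric(length(idx))
    for (m in seq_len(ncol(points))) {
      o <- order(points[idx, m])
      span <- points[idx[o[length(o)]], m] - points[idx[o[1L]], m]
      cd[o[1L]] <- Inf
      cd[o[length(o)]] <- Inf
      if (span > 0) {
        for (k in 2L:(length(o) - 1L)) {
          cd[o[k]] <- cd[o[k]] +
            (points[idx[o[k + 1L]], m] - points[idx[o[k - 1L]], m]) / span
        }
      }
    }
    crowding[idx] <- crowding[idx] + cd
  }
  list(rank = rank, crowding = crowding)
}

sbx_crossover <- function(p1, p2, lower, upper, eta = 15, prob = 0.9) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < prob) {
    for (i in seq_along(p1)) {
      if (stats::runif(1) > 0.5) next
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
        (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[i] <- 0.5 * ((1 + beta) * p1[i] + (1 - beta) * p2[i])
      c2[i] <- 0.5 * ((1 - beta) * p1[i] + (1 + beta) * p2[i])
    }
  }
  c1 <- pmin(pmax(c1, lower), upper)
  c2 <- pmin(pmax(c2, lower), upper)
  list(c1, c2)
}

poly_mutation <- function(p, lower, upper, eta = 20, prob = NULL,
                          zero_prob = 0.2) {
  if (is.null(prob)) prob <- 1 / length(p)
  for (i in seq_along(p)) {
    if (stats::runif(1) >= prob) next
    if (stats::runif(1) < zero_prob) {
      # sparsity move: switch the gene off entirely so single-feature
      # modifications are reachable despite real-coded variation
      p[i] <- 0
      next
    }
    span <- upper[i] - lower[i]
    if (span <= 0) next
    r <- stats::runif(1)
    d <- if (r < 0.5) (2 * r)^(1 / (eta + 1)) - 1 else
      1 - (2 * (1 - r))^(1 / (eta + 1))
    p[i] <- min(max(p[i] + d * span, lower[i]), upper[i])
  }
  p
}

#' Recommend minimal admissible modifications (NSGA-II)
#'
#' Searches for modifications of the modifiable features that flip the
#' feeling-of-health prediction from bad to good, minimizing the two
#' objectives (modification volume, number of changed features) with an
#' elitist NSGA-II (non-dominated sorting + crowding distance, simulated
#' binary crossover, polynomial mutation with an explicit gene-zeroing
#' sparsity move). Inadmissible candidates are handled by constrained
#' domination: any admissible candidate outranks any inadmissible one.
#' Correlated features are propagated through the partition's linear models
#' before every admissibility check.
#'
#' @param record One-row data frame predicted `"bad"` by the model (a
#'   record already predicted good returns an empty front with status
#'   `"already-good"`).
#' @param model A `health_model`.
#' @param partition A `feature_partition` with fitted models.
#' @param bounds Named list (per modifiable feature) of `c(lower, upper)`
#'   delta bounds.
#' @param nsga_config Named list overriding `pop_size` (100),
#'   `generations` (100), `crossover_eta` (15), `crossover_prob` (0.9),
#'   `mutation_eta` (20), `mutation_prob` (1/n_vars), `init_nonzero_prob`
#'   (0.3), `zero_prob` (0.2).
#' @param seed Integer seed.
#' @return A `pareto_front` object: `solutions` (data frame of deltas with
#'   `volume` and `n_changed`, deduplicated, mutually non-dominated, all
#'   admissible), `status` (`"ok"`, `"already-good"` or
#'   `"no-suitable-modification"`), and the candidate records in
#'   `candidates`.
#' @export
recommend <- function(record, model, partition, bounds,
                      nsga_config = list(), seed = 1L) {
  cfg <- utils::modifyList(
    list(pop_size = 100L, generations = 100L, crossover_eta = 15,
         crossover_prob = 0.9, mutation_eta = 20, mutation_prob = NULL,
         init_nonzero_prob = 0.3, zero_prob = 0.2),
    nsga_config)
  vars <- partition$modifiable
  stopifnot(all(vars %in% names(bounds)))
  if (predict(model, as.data.frame(record))[1L] == "good") {
    return(structure(list(solutions = empty_front_df(vars), status = "already-good",
                          candidates = NULL), class = "pareto_front"))
  }
  lower <- vapply(bounds[vars], `[`, numeric(1), 1L)
  upper <- vapply(bounds[vars], `[`, numeric(1), 2L)
  ranges <- model$ranges[vars]
  nv <- length(vars)
  mut_prob <- cfg$mutation_prob %||% (1 / nv)
  set.seed(seed)

  # numerical dust from real-coded variation must not count as a changed
  # feature: snap deltas below 1e-9 of the feature range to exact zero
  snap <- function(pop) {
    tiny <- sweep(abs(pop), 2L, 1e-9 * ranges, "<")
    pop[tiny] <- 0
    pop
  }

  eval_pop <- function(pop) {
    # pop: matrix pop_size x nv of deltas
    cand <- as.data.frame(record)[rep(1L, nrow(pop)), , drop = FALSE]
    rownames(cand) <- NULL
    for (k in seq_len(nrow(pop))) {
      d <- stats::setNames(pop[k, ], vars)
      cand[k, ] <- propagate(record, d, partition)
    }
    adm <- predict(model, cand) == "good"
    vol <- rowSums(sweep(abs(pop), 2L, ranges, "/"))
    nch <- rowSums(pop != 0)
    list(obj = cbind(volume = vol, n_changed = nch), admissible = adm,
         candidates = cand)
  }

  init <- matrix(0, cfg$pop_size, nv)
  for (k in seq_len(cfg$pop_size)) {
    on <- stats::runif(nv) < cfg$init_nonzero_prob
    if (!any(on)) on[sample.int(nv, 1L)] <- TRUE
    init[k, on] <- stats::runif(sum(on), lower[on], upper[on])
  }
  pop <- snap(init)
  ev <- eval_pop(pop)

  rank_pop <- function(obj, adm) {
    # constrained domination: admissible before inadmissible, then fronts
    rank <- rep(NA_real_, nrow(obj))
    crowd <- rep(0, nrow(obj))
    if (any(adm)) {
      s <- nondominated_sort(obj[adm, , drop = FALSE])
      rank[adm] <- s$rank
      crowd[adm] <- s$crowding
    }
    if (any(!adm)) {
      s <- nondominated_sort(obj[!adm, , drop = FALSE])
      rank[!adm] <- s$rank + max(c(0, rank[adm]), na.rm = TRUE)
      crowd[!adm] <- s$crowding
    }
    list(rank = rank, crowding = crowd)
  }

  for (g in seq_len(cfg$generations)) {
    rc <- rank_pop(ev$obj, ev$admissible)
    # binary tournament on (rank, crowding)
    pick <- function() {
      a <- sample.int(nrow(pop), 2L)
      if (rc$rank[a[1L]] < rc$rank[a[2L]]) a[1L]
      else if (rc$rank[a[2L]] < rc$rank[a[1L]]) a[2L]
      else if (rc$crowding[a[1L]] >= rc$crowding[a[2L]]) a[1L] else a[2L]
    }
    off <- matrix(0, cfg$pop_size, nv)
    k <- 1L
    while (k <= cfg$pop_size) {
      ch <- sbx_crossover(pop[pick(), ], pop[pick(), ], lower, upper,
                          cfg$crossover_eta, cfg$crossover_prob)
      off[k, ] <- poly_mutation(ch[[1L]], lower, upper, cfg$mutation_eta,
                                mut_prob, cfg$zero_prob)
      if (k + 1L <= cfg$pop_size) {
        off[k + 1L, ] <- poly_mutation(ch[[2L]], lower, upper,
                                       cfg$mutation_eta, mut_prob,
                                       cfg$zero_prob)
      }
      k <- k + 2L
    }
    off <- snap(off)
    ev_off <- eval_pop(off)
    comb <- rbind(pop, off)
    obj <- rbind(ev$obj, ev_off$obj)
    adm <- c(ev$admissible, ev_off$admissible)
    cand <- rbind(ev$candidates, ev_off$candidates)
    rc2 <- rank_pop(obj, adm)
    ord <- order(rc2$rank, -rc2$crowding)
    sel <- ord[seq_len(cfg$pop_size)]
    pop <- comb[sel, , drop = FALSE]
    ev <- list(obj = obj[sel, , drop = FALSE], admissible = adm[sel],
               candidates = cand[sel, , drop = FALSE])
  }

  if (!any(ev$admissible)) {
    return(structure(list(solutions = empty_front_df(vars),
                          status = "no-suitable-modification",
                          candidates = NULL), class = "pareto_front"))
  }
  apop <- pop[ev$admissible, , drop = FALSE]
  aobj <- ev$obj[ev$admissible, , drop = FALSE]
  acand <- ev$candidates[ev$admissible, , drop = FALSE]
  s <- nondominated_sort(aobj)
  keep <- s$rank == 1L
  apop <- apop[keep, , drop = FALSE]
  aobj <- aobj[keep, , drop = FALSE]
  acand <- acand[keep, , drop = FALSE]
  key <- apply(round(apop, 6L), 1L, paste, collapse = "|")
  dup <- duplicated(key)
  apop <- apop[!dup, , drop = FALSE]
  aobj <- aobj[!dup, , drop = FALSE]
  acand <- acand[!dup, , drop = FALSE]
  sol <- as.data.frame(apop)
  names(sol) <- paste0("delta_", vars)
  sol$volume <- aobj[, "volume"]
  sol$n_changed <- as.integer(aobj[, "n_changed"])
  ord <- order(sol$n_changed, sol$volume)
  sol <- sol[ord, , drop = FALSE]
  acand <- acand[ord, , drop = FALSE]
  rownames(sol) <- rownames(acand) <- NULL
  structure(list(solutions = sol, status = "ok", candidates = acand),
            class = "pareto_front")
}

empty_front_df <- function(vars) {
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(vars)),
                                       paste0("delta_", vars)))
  out$volume <- numeric(0)
  out$n_changed <- integer(0)
  out
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> status: %s, %d solution(s)\n", x$status,
              nrow(x$solutions)))
  if (nrow(x$solutions) > 0L) print(x$solutions, row.names = FALSE, digits = 4)
  invisible(x)
}
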