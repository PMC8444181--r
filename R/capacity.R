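#' Per-dose response samples of a signalling channel
#'
#' Bundles the discrete channel input (the Hy-IL-6 dose ladder) with the
#' continuous per-cell responses (log10 pSTAT3) observed at each dose, for
#' one (genotype, time, replicate).
#'
#' @param input_levels ordered vector of unique doses (ng/ml), length >= 2.
#' @param responses list of numeric vectors, one per level (log10 a.u.).
#' @param condition optional metadata list/data.frame.
#' @return object of class `channel_samples`.
#' @export
channel_samples <- function(input_levels, responses, condition = NULL) {
  stopifnot(length(input_levels) >= 2L, length(responses) == length(input_levels))
  if (anyDuplicated(input_levels)) {
    stop("input levels must be unique", call. = FALSE)
  }
  sizes <- vapply(responses, length, integer(1))
  if (any(sizes < 1L)) {
    stop("every input level needs at least one response", call. = FALSE)
  }
  ord <- order(input_levels)
  structure(
    list(
      input_levels = input_levels[ord], responses = responses[ord],
      condition = condition
    ),
    class = "channel_samples"
  )
}

#' Build channel samples from an event table
#'
#' Groups one (genotype, time, replicate) table by dose and takes
#' log10-floored pSTAT3 as the response.
#'
#' @param events an [event_table()] for a single genotype/time/replicate.
#' @param floor intensity floor for the log transform.
#' @return a [channel_samples()] object.
#' @export
channel_samples_from_events <- function(events, floor = 1) {
  events <- validate_event_table(events)
  if (length(unique(events$genotype)) > 1L ||
    length(unique(events$time_min)) > 1L ||
    length(unique(events$replicate)) > 1L) {
    stop("events must come from a single genotype/time/replicate",
      call. = FALSE
    )
  }
  lg <- if (isTRUE(attr(events, "log10"))) events else log_transform(events, floor)
  sp <- split(lg$pstat3, lg$dose_ng_ml) # split() orders numeric keys ascending
  channel_samples(as.numeric(names(sp)), unname(sp),
    condition = condition_meta(events)[c("genotype", "time_min", "replicate")]
  )
}

#' Per-level conditional response densities on a shared grid
#'
#' One 1-D Gaussian kernel estimate per input level ([fit_kde()]),
#' evaluated on a single grid spanning the pooled response range plus 3
#' maximal bandwidths — the discretised channel matrix that
#' [blahut_arimoto()] maximises over.
#'
#' @param channel a [channel_samples()] object.
#' @param grid_size number of grid points (default 512; discretisation
#'   error is far below the estimator tolerances at this resolution for
#'   smooth kernel conditionals).
#' @param min_n minimum samples per level (default 100).
#' @return list with `grid`, `grid_step`, `dens` (levels x grid matrix of
#'   conditional densities), `input_levels`, `condition`; class
#'   `channel_conditionals`.
#' @export
conditional_densities <- function(channel, grid_size = 512L, min_n = 100L) {
  stopifnot(inherits(channel, "channel_samples"))
  sizes <- vapply(channel$responses, length, integer(1))
  small <- sizes < min_n
  if (any(small)) {
    stop(
      "input level(s) below min_n = ", min_n, " samples: dose ",
      paste(channel$input_levels[small], collapse = ", "), " ng/ml",
      call. = FALSE
    )
  }
  kdes <- lapply(channel$responses, fit_kde)
  bw <- vapply(kdes, function(k) sqrt(k$H[1L, 1L]), numeric(1))
  lo <- min(unlist(channel$responses)) - 3 * max(bw)
  hi <- max(unlist(channel$responses)) + 3 * max(bw)
  grid <- seq(lo, hi, length.out = grid_size)
  dens <- t(vapply(kdes, function(k) kde_evaluate(k, grid),
    numeric(grid_size)
  ))
  rownames(dens) <- as.character(channel$input_levels)
  structure(
    list(
      grid = grid, grid_step = grid[2L] - grid[1L], dens = dens,
      input_levels = channel$input_levels, condition = channel$condition
    ),
    class = "channel_conditionals"
  )
}

new_cc_result <- function(cc_bits, optimal_input, method, iterations,
                          converged, condition, trace = NULL) {
  structure(
    list(
      cc_bits = cc_bits, optimal_input = optimal_input,
      n_states = 2^cc_bits, method = method, iterations = iterations,
      converged = converged, condition = condition, capacity_trace = trace
    ),
    class = "cc_result"
  )
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf(
    "Channel capacity = %.4f bits (2^CC = %.3f states; %s, %d iterations%s)\n",
    x$cc_bits, x$n_states, x$method, x$iterations,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' Channel capacity by Blahut-Arimoto iteration
#'
#' Maximises mutual information over the distribution of the discrete input
#' (`CC = max over p(S) of MI(S;R)`) for a channel given by per-level
#' conditional response densities on a common grid. The classical
#' alternating update: with input weights `p`, compute the output mixture
#' `q(r)`, then the per-level divergence `D_s = sum_r p(r|s) ln[p(r|s)/q(r)]`,
#' and reweight `p'_s = p_s exp(D_s) / Z`. The capacity sequence is
#' nondecreasing (asserted every run) and the iteration stops when the
#' change drops below `tol` bits.
#'
#' @param conditionals a [conditional_densities()] result, or a list with a
#'   `dens` matrix (rows = levels, columns = response grid) and `grid_step`.
#' @param tol convergence tolerance in bits (default 1e-7).
#' @param max_iter iteration cap (default 1e4).
#' @return a `cc_result`; `n_states = 2^cc_bits` is the number of input
#'   states distinguishable from the response.
#' @export
blahut_arimoto <- function(conditionals, tol = 1e-7, max_iter = 1e4) {
  dens <- conditionals$dens
  if (!all(is.finite(dens)) || any(dens < 0)) {
    stop("conditional densities must be finite and nonnegative",
      call. = FALSE
    )
  }
  k <- nrow(dens)
  if (k < 2L) stop("need at least 2 input levels", call. = FALSE)
  Q <- dens * conditionals$grid_step
  Q <- Q / rowSums(Q) # row-stochastic transition matrix on the grid
  p <- rep(1 / k, k)
  cap_prev <- -Inf
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    q <- as.vector(p %*% Q)
    ratio <- sweep(Q, 2L, pmax(q, 1e-300), "/")
    lr <- ifelse(Q > 0, log(ratio), 0)
    D <- rowSums(Q * lr) # nats
    cap <- sum(p * D) / log(2)
    trace <- c(trace, cap)
    if (cap < cap_prev - 1e-10) {
      stop("Blahut-Arimoto capacity sequence decreased: numerical failure",
        call. = FALSE
      )
    }
    if (is.finite(cap_prev) && cap - cap_prev < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    cap_prev <- cap
    p <- p * exp(D - max(D))
    p <- p / sum(p)
  }
  names(p) <- rownames(dens)
  new_cc_result(max(cap, 0), p,
    method = "blahut_arimoto",
    iterations = iter, converged = converged,
    condition = conditionals$condition, trace = trace
  )
}

#' Brute-force capacity of a two-level channel by grid search
#'
#' Independent reference for [blahut_arimoto()] on binary-input channels:
#' sweeps the weight of the first input over a fine grid (default step
#' 1e-3) and evaluates MI for each weight by quadrature on the shared
#' response grid. No alternating optimisation is involved.
#'
#' @param conditionals a [conditional_densities()] result with exactly 2
#'   levels.
#' @param step weight grid step.
#' @return list with `cc_bits` and `w_opt` (optimal weight of level 1).
#' @export
binary_capacity_grid <- function(conditionals, step = 1e-3) {
  dens <- conditionals$dens
  stopifnot(nrow(dens) == 2L)
  d1 <- dens[1L, ] * conditionals$grid_step
  d2 <- dens[2L, ] * conditionals$grid_step
  d1 <- d1 / sum(d1)
  d2 <- d2 / sum(d2)
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / pmax(b[nz], 1e-300)))
  }
  ws <- seq(0, 1, by = step)
  mi <- vapply(ws, function(w) {
    q <- w * d1 + (1 - w) * d2
    w * kl(d1, q) + (1 - w) * kl(d2, q)
  }, numeric(1))
  list(cc_bits = max(mi), w_opt = ws[which.max(mi)])
}

#' Channel capacity by regularised classification
#'
#' Re-implementation of the statistical-learning capacity estimator: fit a
#' regularised multinomial logistic model for the input posterior
#' `P(S | R)` with out-of-fold (cross-validated) predictions, estimate MI
#' for given input weights by the Monte-Carlo average of
#' `log2 P(S_i | R_i) / p(S_i)` over held-out cells, and maximise over the
#' input weights by Blahut-Arimoto-style reweighting of the posterior
#' ratios. The logistic model uses a polynomial basis in the response
#' (default degree 2, so unequal-variance channels are representable) and
#' L2 weight decay.
#'
#' @param channel a [channel_samples()] object.
#' @param folds number of stratified cross-validation folds (default 10).
#' @param decay L2 regularisation strength passed to [nnet::multinom()]
#'   (default 1).
#' @param degree polynomial degree of the response basis (default 2).
#' @param tol reweighting convergence tolerance in bits.
#' @param max_iter reweighting iteration cap.
#' @param min_n minimum samples per level.
#' @param seed seed controlling fold assignment.
#' @return a `cc_result` with `method = "classifier"`.
#' @export
capacity_classifier <- function(channel, folds = 10L, decay = 1, degree = 2L,
                                tol = 1e-6, max_iter = 2000L, min_n = 100L,
                                seed = 1L) {
  stopifnot(inherits(channel, "channel_samples"))
  sizes <- vapply(channel$responses, length, integer(1))
  if (any(sizes < min_n)) {
    stop(
      "input level(s) below min_n = ", min_n, " samples: dose ",
      paste(channel$input_levels[sizes < min_n], collapse = ", "), " ng/ml",
      call. = FALSE
    )
  }
  if (folds < 2L || folds > min(sizes)) {
    stop(
      "stratification failed: ", folds, " folds cannot each keep the ",
      "smallest input level (n = ", min(sizes), ")",
      call. = FALSE
    )
  }
  k <- length(channel$input_levels)
  r <- unlist(channel$responses)
  lab <- factor(
    rep(seq_len(k), times = sizes),
    levels = seq_len(k)
  )
  n <- length(r)
  # stratified folds
  fold <- integer(n)
  fold_assign <- with_seed(seed, {
    for (s in seq_len(k)) {
      idx <- which(lab == levels(lab)[s])
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
  # raw polynomial basis on the standardised response: coefficients stay
  # O(1), so the weight-decay penalty is commensurate across sample sizes
  rs <- scale(r)[, 1L]
  df <- data.frame(lab = lab)
  for (p in seq_len(degree)) df[[paste0("r", p)]] <- rs^p
  post <- matrix(NA_real_, n, k)
  for (f in seq_len(folds)) {
    train <- df[fold_assign != f, , drop = FALSE]
    if (length(unique(train$lab)) < k) {
      stop("fold ", f, " lost an input level: stratification failed",
        call. = FALSE
      )
    }
    fit <- nnet::multinom(lab ~ ., data = train, decay = decay,
      trace = FALSE, maxit = 500
    )
    pr <- stats::predict(fit, newdata = df[fold_assign == f, , drop = FALSE],
      type = "probs"
    )
    if (k == 2L) pr <- cbind(1 - pr, pr) # multinom returns P(level 2) for k = 2
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = k) # single held-out row
    post[fold_assign == f, ] <- pr
  }
  post <- pmax(post, 1e-12)
  post <- post / rowSums(post)
  p0 <- as.vector(table(lab)) / n # sampling frequencies behind the posterior

  # maximise MC mutual information over input weights q:
  # P_q(s|R) propto post(s|R) * q_s / p0_s; D_s = E[ln P_q(s|R_i)/q_s | S = s]
  q <- rep(1 / k, k)
  cap_prev <- -Inf
  iter <- 0L
  converged <- FALSE
  cls_idx <- split(seq_len(n), lab)
  repeat {
    iter <- iter + 1L
    W <- sweep(post, 2L, q / p0, "*")
    W <- W / rowSums(W)
    D <- vapply(seq_len(k), function(s) {
      mean(log(pmax(W[cls_idx[[s]], s], 1e-300) / q[s]))
    }, numeric(1))
    cap <- sum(q * D) / log(2)
    if (is.finite(cap_prev) && abs(cap - cap_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    cap_prev <- cap
    q <- q * exp(D - max(D))
    q <- q / sum(q)
  }
  names(q) <- as.character(channel$input_levels)
  new_cc_result(max(cap, 0), q,
    method = "classifier", iterations = iter,
    converged = converged, condition = channel$condition
  )
}

#' Number of distinguishable input states
#'
#' `2^CC`: the number of input states (here, cytokine doses) that can be
#' discriminated with high confidence from the response.
#'
#' @param result a `cc_result`.
#' @return `2^cc_bits` (>= 1).
#' @export
n_distinguishable_states <- function(result) {
  stopifnot(inherits(result, "cc_result"))
  2^result$cc_bits
}

#' Per-replicate channel capacity for a study
#'
#' One capacity estimate per (genotype, time, replicate), assembled from
#' that replicate's per-dose response samples. Every replicate must carry
#' the full dose ladder present in the study.
#'
#' @param study a [generate_study()] result, list of event tables, or
#'   combined [event_table()].
#' @param time `"early"`, `"late"`, `15`, `90`, or `NULL` for all times.
#' @param method `"ba"` (Blahut-Arimoto, default) or `"classifier"`.
#' @param grid_size,min_n passed to [conditional_densities()].
#' @param ... further options for [capacity_classifier()].
#' @return data.frame with columns `genotype`, `time_min`, `replicate`,
#'   `method`, `cc_bits`, `n_states`, `converged`.
#' @export
cc_per_condition <- function(study, time = NULL, method = c("ba", "classifier"),
                             grid_size = 512L, min_n = 100L, ...) {
  method <- match.arg(method)
  tab <- if (is.data.frame(study)) validate_event_table(study) else study_table(study)
  if (!is.null(time)) {
    tab <- tab[tab$time_min == time_to_min(time), , drop = FALSE]
    if (!nrow(tab)) stop("no events at the requested time", call. = FALSE)
  }
  ladder <- sort(unique(tab$dose_ng_ml))
  if (length(ladder) < 2L) {
    stop("study carries fewer than 2 dose levels", call. = FALSE)
  }
  key <- interaction(tab$genotype, tab$time_min, tab$replicate,
    drop = TRUE, sep = "|"
  )
  groups <- split(as.data.frame(tab), key)
  rows <- lapply(names(groups), function(gk) {
    g <- validate_event_table(groups[[gk]])
    have <- sort(unique(g$dose_ng_ml))
    if (!identical(have, ladder)) {
      stop(
        "condition ", gk, " is missing dose level(s): ",
        paste(setdiff(ladder, have), collapse = ", "), " ng/ml",
        call. = FALSE
      )
    }
    ch <- channel_samples_from_events(g)
    res <- if (method == "ba") {
      blahut_arimoto(conditional_densities(ch, grid_size, min_n))
    } else {
      capacity_classifier(ch, min_n = min_n, ...)
    }
    data.frame(
      genotype = as.character(g$genotype[1L]),
      time_min = g$time_min[1L],
      replicate = as.character(g$replicate[1L]),
      method = res$method,
      cc_bits = res$cc_bits,
      n_states = res$n_states,
      converged = res$converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
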