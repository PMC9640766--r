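# Neuron-level analyses of recorded policy-layer activity: condition
# firing-rate tables, category index (CI) and stimulus index (SI),
# permutation (bootstrap) significance, neuron taxonomy, connectivity
# split, learning time courses, weight analyses and action coding.

.COND6 <- c("A1", "B1", "C1", "A2", "B2", "C2")

#' Analysis windows over the trial
#'
#' Step ranges (1-based indices into the time dimension of recorded
#' rate arrays) for the analysis windows: a baseline (-200 to 0 ms from
#' first-stimulus onset), the five task periods used for index time
#' courses (first stimulus 0-400 ms from onset, first delay, second
#' stimulus, second delay, third stimulus), the first decision window
#' and the combined first stimulus + delay window.
#'
#' @param schedule Event schedule.
#' @return List with `names` (the five periods plus baseline) and
#'   `steps` (named list of step-index vectors).
#' @export
analysis_windows <- function(schedule = build_schedule()) {
  p <- schedule$periods
  rng <- function(name) (p$start[p$name == name] + 1L):p$end[p$name == name]
  base_len <- 200 / schedule$dt
  fs <- rng("first_stimulus")
  steps <- list(
    baseline = max(1L, fs[1] - base_len):(fs[1] - 1L),
    first_stimulus = fs,
    first_delay = rng("first_delay"),
    second_stimulus = rng("second_stimulus"),
    second_delay = rng("mid_fixation"),
    third_stimulus = rng("third_stimulus"),
    first_decision = rng("first_decision"),
    stim_delay = c(rng("first_stimulus"), rng("first_delay")))
  list(names = names(steps), steps = steps,
       periods = c("first_stimulus", "first_delay", "second_stimulus",
                   "second_delay", "third_stimulus"))
}

#' Trial-condition label: the stimulus shown first
#'
#' Each of the six stimuli appears as the first (sample) stimulus in
#' exactly one sequence order, so pooling trials by first stimulus
#' yields the six condition means the indexes are built from.
#'
#' @param trials Trial data frame with `order` and `group`.
#' @return Factor with levels A1, B1, C1, A2, B2, C2.
#' @export
first_stimulus_label <- function(trials) {
  letter <- vapply(as.character(trials$order),
                   function(o) .ORDER_LETTERS[[o]][1], character(1))
  factor(paste0(letter, trials$group), levels = .COND6)
}

#' Mean firing rate per neuron and condition
#'
#' Averages each neuron's window-averaged rate over the trials of each
#' first-stimulus condition (correct trials only by default, matching
#' analysis of the learned network on frozen test blocks).
#'
#' @param record An [evaluate_agent()] recording (`record = TRUE`).
#' @param window Window name from [analysis_windows()].
#' @param correct_only Restrict to trials with both choices correct.
#' @return A `rate_table` list: `means` (neuron x 6 matrix), `counts`
#'   (trials per condition), `trial_rates` (trial x neuron matrix for
#'   the window), `labels` (per-trial condition factor), `window`.
#' @export
mean_rates <- function(record, window = "first_stimulus",
                       correct_only = TRUE) {
  keep <- if (correct_only) record$trials$correct else
    rep(TRUE, nrow(record$trials))
  labels <- first_stimulus_label(record$trials)[keep]
  tr <- record$win_rates[keep, , window]
  counts <- table(labels)
  if (any(counts == 0)) {
    warning("empty condition(s): ", paste(names(counts)[counts == 0],
                                          collapse = ", "))
  }
  sums <- rowsum(tr, labels)
  means <- t(sums / as.vector(counts))
  colnames(means) <- .COND6
  structure(list(means = means, counts = as.vector(counts),
                 trial_rates = tr, labels = labels, window = window),
            class = "rate_table")
}

#' Category index from six condition means
#'
#' Within-category difference WCD averages the six absolute pairwise
#' rate differences inside the two groups; between-category difference
#' BCD averages the nine cross-group pairs; CI = (BCD - WCD) /
#' (BCD + WCD), in \[-1, 1\].  Neurons with BCD + WCD = 0 have an
#' undefined CI (returned as NA).
#'
#' @param means Numeric vector of 6 condition means in the order A1,
#'   B1, C1, A2, B2, C2, or a neuron x 6 matrix.
#' @return For a vector: list with `FD_A1`, `FD_A2`, `WCD`, `FD1`,
#'   `FD2`, `FD3`, `BCD`, `CI`.  For a matrix: numeric vector of CI
#'   values (one per row).
#' @export
category_index <- function(means) {
  if (is.matrix(means)) return(.ci_matrix(means))
  x <- as.numeric(means)
  FD_A1 <- abs(x[1] - x[2]) + abs(x[1] - x[3]) + abs(x[2] - x[3])
  FD_A2 <- abs(x[4] - x[5]) + abs(x[4] - x[6]) + abs(x[5] - x[6])
  WCD <- (FD_A1 + FD_A2) / 6
  FD1 <- abs(x[1] - x[4]) + abs(x[1] - x[5]) + abs(x[1] - x[6])
  FD2 <- abs(x[2] - x[4]) + abs(x[2] - x[5]) + abs(x[2] - x[6])
  FD3 <- abs(x[3] - x[4]) + abs(x[3] - x[5]) + abs(x[3] - x[6])
  BCD <- (FD1 + FD2 + FD3) / 9
  CI <- if (BCD + WCD > 0) (BCD - WCD) / (BCD + WCD) else NA_real_
  list(FD_A1 = FD_A1, FD_A2 = FD_A2, WCD = WCD,
       FD1 = FD1, FD2 = FD2, FD3 = FD3, BCD = BCD, CI = CI)
}

# vectorised CI over rows of a neuron x 6 matrix
.ci_matrix <- function(m) {
  w <- (abs(m[, 1] - m[, 2]) + abs(m[, 1] - m[, 3]) + abs(m[, 2] - m[, 3]) +
        abs(m[, 4] - m[, 5]) + abs(m[, 4] - m[, 6]) + abs(m[, 5] - m[, 6])) / 6
  b <- (abs(m[, 1] - m[, 4]) + abs(m[, 1] - m[, 5]) + abs(m[, 1] - m[, 6]) +
        abs(m[, 2] - m[, 4]) + abs(m[, 2] - m[, 5]) + abs(m[, 2] - m[, 6]) +
        abs(m[, 3] - m[, 4]) + abs(m[, 3] - m[, 5]) + abs(m[, 3] - m[, 6])) / 9
  ifelse(b + w > 0, (b - w) / (b + w), NA_real_)
}

#' Stimulus index from six condition means
#'
#' Per group, (max - min) / (max + min) over the three within-group
#' means; SI is the average of the two group components, in \[0, 1\].
#' A component with max + min = 0 is undefined (NA).
#'
#' @param means Vector of 6 condition means (A1, B1, C1, A2, B2, C2)
#'   or a neuron x 6 matrix.
#' @return For a vector: list with `SI_A1`, `SI_A2`, `SI`; for a
#'   matrix: numeric vector of SI values.
#' @export
stimulus_index <- function(means) {
  if (is.matrix(means)) return(.si_matrix(means))
  x <- as.numeric(means)
  comp <- function(g) {
    mx <- max(g); mn <- min(g)
    if (mx + mn > 0) (mx - mn) / (mx + mn) else NA_real_
  }
  SI_A1 <- comp(x[1:3]); SI_A2 <- comp(x[4:6])
  list(SI_A1 = SI_A1, SI_A2 = SI_A2, SI = (SI_A1 + SI_A2) / 2)
}

.si_matrix <- function(m) {
  g1 <- m[, 1:3, drop = FALSE]; g2 <- m[, 4:6, drop = FALSE]
  mx1 <- apply(g1, 1, max); mn1 <- apply(g1, 1, min)
  mx2 <- apply(g2, 1, max); mn2 <- apply(g2, 1, min)
  s1 <- ifelse(mx1 + mn1 > 0, (mx1 - mn1) / (mx1 + mn1), NA_real_)
  s2 <- ifelse(mx2 + mn2 > 0, (mx2 - mn2) / (mx2 + mn2), NA_real_)
  (s1 + s2) / 2
}

#' Permutation (bootstrap) significance of the category index
#'
#' For each neuron the per-trial window rates are shuffled among the
#' six first-stimulus conditions (trial-to-condition labels permuted
#' uniformly, independently per neuron), the CI recomputed per shuffle,
#' and the observed CI deemed significant when it falls in the top or
#' bottom 2.5% of the shuffled distribution.  A shuffle with undefined
#' CI is recorded as 0 and counted.
#'
#' @param trial_rates Trial x neuron matrix of window-averaged rates
#'   (or a vector for one neuron).
#' @param labels Per-trial condition factor (levels A1..C2).
#' @param n_shuffles Number of label permutations.
#' @return Data frame per neuron: `ci` (observed), `p` (two-tailed
#'   empirical tail proportion) and `significant`.
#' @export
bootstrap_significance <- function(trial_rates, labels, n_shuffles = 500) {
  if (is.vector(trial_rates)) trial_rates <- matrix(trial_rates, ncol = 1)
  labels <- factor(labels, levels = .COND6)
  if (min(table(labels)) < 2) stop("need >= 2 trials per condition",
                                   call. = FALSE)
  counts <- as.vector(table(labels))
  nn <- ncol(trial_rates)
  obs_means <- t(rowsum(trial_rates, labels) / counts)
  ci_obs <- .ci_matrix(obs_means)
  n_hi <- numeric(nn); n_lo <- numeric(nn)
  nt <- nrow(trial_rates)
  for (s in seq_len(n_shuffles)) {
    perm <- apply(trial_rates, 2, function(col) col[sample.int(nt)])
    m <- t(rowsum(perm, labels) / counts)
    ci_s <- .ci_matrix(m)
    ci_s[is.na(ci_s)] <- 0
    n_hi <- n_hi + (ci_s >= ci_obs)
    n_lo <- n_lo + (ci_s <= ci_obs)
  }
  p <- pmin(1, 2 * pmin(n_hi, n_lo) / n_shuffles)
  data.frame(ci = ci_obs, p = p,
             significant = !is.na(ci_obs) & p < 0.05)
}

#' Classify neurons as silent, stimulus-coding or category-coding
#'
#' Silent neurons have exactly zero rate at every step of every
#' analysed trial; among the rest, neurons with a bootstrap-significant
#' CI are category-neurons and the others stimulus-neurons.  Neurons
#' with an undefined CI (identical means) are flagged `excluded`.
#'
#' @param record An [evaluate_agent()] recording.
#' @param n_shuffles Permutations for the significance test.
#' @param window Analysis window for the indexes.
#' @param silent_tol Rate threshold below which a neuron's maximum
#'   activity counts as silent (default exactly 0).
#' @return Data frame per neuron: `neuron`, `class`, `ci`, `si`, `p`,
#'   `significant`, `excluded`.
#' @export
classify_neurons <- function(record, n_shuffles = 500,
                             window = "first_stimulus", silent_tol = 0) {
  rt <- mean_rates(record, window = window)
  boot <- bootstrap_significance(rt$trial_rates, rt$labels, n_shuffles)
  si <- stimulus_index(rt$means)
  silent <- record$max_rate <= silent_tol
  cls <- ifelse(silent, "silent",
                ifelse(boot$significant, "category", "stimulus"))
  data.frame(neuron = seq_len(nrow(rt$means)), class = cls,
             ci = boot$ci, si = si, p = boot$p,
             significant = boot$significant & !silent,
             excluded = !silent & is.na(boot$ci))
}

#' Split neurons by direct input connectivity
#'
#' A policy-layer neuron is "direct" when its input mask row has at
#' least one nonzero entry (it receives at least one input-layer
#' projection), else "indirect".  Group CI/SI summaries are compared
#' with two-sided Mann-Whitney (Wilcoxon rank-sum) tests.
#'
#' @param agent A trained agent (its `policy$M_in` mask is used).
#' @param classes A [classify_neurons()] data frame.
#' @return List: per-neuron `direct` flag, counts, per-group summaries
#'   over category-neurons, and the rank-sum p-values for CI and SI.
#' @export
connectivity_split <- function(agent, classes) {
  direct <- rowSums(agent$policy$M_in) > 0
  classes$direct <- direct
  cat_idx <- classes$class == "category"
  summarise <- function(sel) {
    list(n = sum(sel), n_category = sum(sel & cat_idx),
         mean_ci_category = mean(classes$ci[sel & cat_idx]),
         mean_si_category = mean(classes$si[sel & cat_idx]))
  }
  p_ci <- p_si <- NA_real_
  if (sum(direct & cat_idx) > 1 && sum(!direct & cat_idx) > 1) {
    p_ci <- stats::wilcox.test(classes$ci[direct & cat_idx],
                               classes$ci[!direct & cat_idx],
                               exact = FALSE)$p.value
    p_si <- stats::wilcox.test(classes$si[direct & cat_idx],
                               classes$si[!direct & cat_idx],
                               exact = FALSE)$p.value
  }
  list(direct = direct, n_direct = sum(direct), n_indirect = sum(!direct),
       frac_direct = mean(direct),
       direct_summary = summarise(direct),
       indirect_summary = summarise(!direct),
       p_ci_ranksum = p_ci, p_si_ranksum = p_si,
       neurons = classes)
}

# per-checkpoint condition x window mean-rate summaries (small), used
# for index time courses without storing whole recordings
condition_period_means <- function(record, schedule = build_schedule()) {
  wins <- analysis_windows(schedule)
  keep <- record$trials$correct
  labels <- first_stimulus_label(record$trials)[keep]
  counts <- as.vector(table(labels))
  np <- dim(record$win_rates)[2]
  out <- array(NA_real_, c(np, 6L, length(wins$names)),
               dimnames = list(NULL, .COND6, wins$names))
  if (!any(keep) || any(counts == 0)) {
    attr(out, "counts") <- counts
    return(out)
  }
  for (w in seq_along(wins$names)) {
    tr <- record$win_rates[keep, , wins$names[w]]
    out[, , w] <- t(rowsum(tr, labels) / counts)
  }
  attr(out, "counts") <- counts
  out
}

#' Index time courses over learning and task periods
#'
#' Recomputes CI and SI at every stored test-block checkpoint (class
#' membership fixed at the final-stage classification) and, for the
#' final stage, across the five task periods.
#'
#' @param fit A [train_agent()] fit.
#' @param classes Final-stage [classify_neurons()] data frame.
#' @param group Optional logical vector (e.g. direct-connectivity flag)
#'   used instead of the class labels.
#' @return List of two data frames: `learning` (iteration x class mean
#'   CI/SI in the first stimulus period) and `periods` (final-stage
#'   class means per task period).
#' @export
index_timecourse <- function(fit, classes, group = NULL) {
  lab <- if (is.null(group)) classes$class else
    ifelse(group, "direct", "indirect")
  sel <- split(seq_len(nrow(classes)), lab)
  sel <- sel[setdiff(names(sel), "silent")]
  learning <- do.call(rbind, lapply(fit$checkpoints, function(cp) {
    m <- cp$cond_means[, , "first_stimulus"]
    ci <- .ci_matrix(m); si <- .si_matrix(m)
    do.call(rbind, lapply(names(sel), function(cl) {
      data.frame(iteration = cp$iteration, class = cl,
                 mean_ci = mean(ci[sel[[cl]]], na.rm = TRUE),
                 mean_si = mean(si[sel[[cl]]], na.rm = TRUE))
    }))
  }))
  final <- fit$checkpoints[[length(fit$checkpoints)]]
  wins <- analysis_windows(fit$schedule)
  periods <- do.call(rbind, lapply(wins$periods, function(w) {
    m <- final$cond_means[, , w]
    ci <- .ci_matrix(m); si <- .si_matrix(m)
    do.call(rbind, lapply(names(sel), function(cl) {
      data.frame(period = w, class = cl,
                 mean_ci = mean(ci[sel[[cl]]], na.rm = TRUE),
                 mean_si = mean(si[sel[[cl]]], na.rm = TRUE))
    }))
  }))
  list(learning = learning, periods = periods)
}

#' Weight distributions and activity-similarity vs. weight change
#'
#' Collects the nonzero recurrent weights (candidate, update-gate and
#' reset-gate matrices) before and after training, and for every
#' connected directed pair (j -> i) the Pearson correlation of the two
#' neurons' trial-averaged first-stimulus-period rate traces against
#' the training-induced change of that connection's weight.
#'
#' @param fit A [train_agent()] fit.
#' @param classes Final-stage classification (for per-class subsets).
#' @return List: `weights` (per-matrix nonzero initial/final values),
#'   `pairs` (data frame: from, to, similarity, dweight, pair_class)
#'   and `correlations` (overall / stimulus-only / category-only
#'   Pearson r and p).
#' @export
weight_analyses <- function(fit, classes) {
  pol <- fit$agent$policy
  init <- fit$init_params
  mats <- c("W_rec", "W_rec_phi", "W_rec_psi")
  weights <- lapply(stats::setNames(mats, mats), function(mn) {
    m <- pol$M_rec == 1
    list(initial = init[[paste0("p.", mn)]][m],
         final = pol[[mn]][m])
  })
  trace <- fit$final_record$trace_first
  conn <- which(pol$M_rec == 1, arr.ind = TRUE)   # (to = i, from = j)
  sdv <- apply(trace, 1, stats::sd)
  ok <- sdv[conn[, 1]] > 0 & sdv[conn[, 2]] > 0
  conn <- conn[ok, , drop = FALSE]
  sim <- vapply(seq_len(nrow(conn)), function(k) {
    stats::cor(trace[conn[k, 1], ], trace[conn[k, 2], ])
  }, numeric(1))
  dw <- pol$W_rec[conn] - init$p.W_rec[conn]
  cls <- classes$class
  pair_class <- ifelse(cls[conn[, 1]] == "stimulus" &
                         cls[conn[, 2]] == "stimulus", "stimulus",
                ifelse(cls[conn[, 1]] == "category" &
                         cls[conn[, 2]] == "category", "category", "mixed"))
  pairs <- data.frame(from = conn[, 2], to = conn[, 1],
                      similarity = sim, dweight = dw,
                      pair_class = pair_class)
  corsub <- function(sel) {
    if (sum(sel) < 3) return(list(r = NA_real_, p = NA_real_, n = sum(sel)))
    ct <- stats::cor.test(sim[sel], dw[sel])
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(sel))
  }
  list(weights = weights, pairs = pairs,
       correlations = list(all = corsub(rep(TRUE, nrow(pairs))),
                           stimulus = corsub(pair_class == "stimulus"),
                           category = corsub(pair_class == "category")))
}

#' Action-coding classification of policy-layer neurons
#'
#' On correct test trials aligned at first-stimulus onset, each
#' non-silent neuron is tested for (i) sensitivity to the chosen side
#' (left vs right) in the first decision window (Wilcoxon rank-sum)
#' and (ii) selectivity for the first-stimulus identity in the combined
#' first stimulus + delay window (Kruskal-Wallis across the six
#' stimuli), both at alpha = 0.05.  Classes: `stimulus-only` (ii only),
#' `stimulus-action` (both), `action-only` (i only), `unclassified`
#' (neither, or insufficient trials).
#'
#' @param record An [evaluate_agent()] recording.
#' @param classes A [classify_neurons()] data frame (for silent flags).
#' @param alpha Test level.
#' @return Data frame per neuron: `neuron`, `action_class`,
#'   `p_side`, `p_stim`.
#' @export
action_coding_classes <- function(record, classes, alpha = 0.05) {
  keep <- record$trials$correct
  side <- factor(record$trials$first_choice_side[keep], levels = c("L", "R"))
  stim <- first_stimulus_label(record$trials)[keep]
  dec <- record$win_rates[keep, , "first_decision"]
  early <- record$win_rates[keep, , "stim_delay"]
  np <- ncol(dec)
  enough <- all(table(side) >= 2) && all(table(stim) >= 2)
  out <- data.frame(neuron = seq_len(np),
                    action_class = "unclassified",
                    p_side = NA_real_, p_stim = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(np)) {
    if (classes$class[i] == "silent") { out$action_class[i] <- "silent"; next }
    if (!enough) next
    p_side <- tryCatch(
      stats::wilcox.test(dec[side == "L", i], dec[side == "R", i],
                         exact = FALSE)$p.value, error = function(e) NA_real_)
    p_stim <- tryCatch(
      stats::kruskal.test(early[, i], stim)$p.value,
      error = function(e) NA_real_)
    out$p_side[i] <- p_side; out$p_stim[i] <- p_stim
    s <- isTRUE(p_stim < alpha); a <- isTRUE(p_side < alpha)
    out$action_class[i] <- if (s && a) "stimulus-action"
      else if (s) "stimulus-only"
      else if (a) "action-only"
      else "unclassified"
  }
  out
}

#' Full post-training analysis summary
#'
#' Convenience wrapper running the classification, connectivity split,
#' time courses, weight analyses and action-coding classification on a
#' fit, and returning headline population statistics.
#'
#' @param fit A converged [train_agent()] fit.
#' @param n_shuffles Bootstrap shuffles.
#' @return List of analysis results plus a `summary` list with neuron
#'   counts and mean CI of category- and stimulus-neurons.
#' @export
analyse_fit <- function(fit, n_shuffles = 500) {
  rec <- fit$final_record
  classes <- classify_neurons(rec, n_shuffles = n_shuffles)
  conn <- connectivity_split(fit$agent, classes)
  tc <- index_timecourse(fit, classes)
  wa <- weight_analyses(fit, classes)
  ac <- action_coding_classes(rec, classes)
  is_cat <- classes$class == "category"
  is_stim <- classes$class == "stimulus"
  list(classes = classes, connectivity = conn, timecourse = tc,
       weights = wa, action_coding = ac,
       summary = list(
         n_silent = sum(classes$class == "silent"),
         n_category = sum(is_cat), n_stimulus = sum(is_stim),
         mean_ci_category = mean(classes$ci[is_cat], na.rm = TRUE),
         mean_ci_stimulus = mean(classes$ci[is_stim], na.rm = TRUE),
         min_ci_category = if (any(is_cat))
           min(classes$ci[is_cat], na.rm = TRUE) else NA_real_,
         mean_si_category = mean(classes$si[is_cat], na.rm = TRUE),
         mean_si_stimulus = mean(classes$si[is_stim], na.rm = TRUE)))
}
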