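.criterion_fun <- function(name) {
  switch(name,
         cmi = gtm_cmi, jmi = gtm_jmi, cife = gtm_cife, mrmr = gtm_mrmr,
         stop("unknown criterion '", name,
              "'; expected one of cmi, jmi, cife, mrmr"))
}

#' Greedy forward selection in the generative tree model
#'
#' At each step the remaining candidate with the largest criterion score given
#' the already-selected set is appended; ties are broken toward the earliest
#' variable in the [gtm_variables()] order (actives by index, the child
#' `X1(1)` last). Step 1 selects from the empty conditioning set, i.e. by
#' marginal relevance `I(X_j, Y)`. With `stopping = TRUE`, selection halts
#' before appending a candidate whose winning score is not strictly positive
#' (the positive-value stopping rule); the rule is available for every
#' criterion, although only CIFE produces negative scores in this model.
#'
#' All criteria here are theoretical (quadrature-exact) values, so the trace
#' is fully deterministic.
#'
#' @param spec a [gtm_spec()].
#' @param criterion one of `"cmi"`, `"jmi"`, `"cife"`, `"mrmr"`.
#' @param n_steps number of selection steps, between 1 and `k + 2`.
#' @param stopping apply the positive-value stopping rule?
#' @param cfg a [quad_config()].
#' @return An object of class `"gtm_selection"`: a list with `criterion`,
#'   `selected` (labels in selection order), `stopped_early`, and `steps`, a
#'   list with one entry per step holding `step`, `chosen`, `score` and the
#'   full named `scores` vector over that step's candidates.
#' @examples
#' greedy_select(gtm_spec(2, 2/3), "jmi", n_steps = 3)
#' @export
greedy_select <- function(spec, criterion = c("cmi", "jmi", "cife", "mrmr"),
                          n_steps = spec$k + 2, stopping = FALSE,
                          cfg = quad_config()) {
  stopifnot(inherits(spec, "gtm_spec"))
  if (is.character(criterion) && length(criterion) == 1 &&
      !criterion %in% c("cmi", "jmi", "cife", "mrmr")) {
    stop("unknown criterion '", criterion,
         "'; expected one of cmi, jmi, cife, mrmr")
  }
  criterion <- match.arg(criterion)
  score_fun <- .criterion_fun(criterion)
  if (n_steps < 1 || n_steps > spec$k + 2) {
    stop("'n_steps' must be between 1 and k + 2 = ", spec$k + 2)
  }
  remaining <- gtm_variables(spec)
  selected <- character(0)
  steps <- vector("list", n_steps)
  stopped_early <- FALSE
  for (s in seq_len(n_steps)) {
    scores <- vapply(remaining, function(j) score_fun(spec, j, selected, cfg),
                     numeric(1))
    best <- which.max(scores)        # ties resolve to the earliest candidate
    if (stopping && scores[best] <= 0) {
      stopped_early <- TRUE
      steps <- steps[seq_len(s - 1)]
      break
    }
    steps[[s]] <- list(step = s, chosen = remaining[best],
                       score = unname(scores[best]), scores = scores)
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  structure(list(criterion = criterion, selected = selected,
                 stopped_early = stopped_early, steps = steps),
            class = "gtm_selection")
}

#' @export
print.gtm_selection <- function(x, ...) {
  cat(sprintf("Greedy forward selection, criterion = %s%s\n", x$criterion,
              if (x$stopped_early) " (stopped early)" else ""))
  for (st in x$steps) {
    cat(sprintf("  step %d: %-6s score %+.6f\n", st$step, st$chosen, st$score))
  }
  invisible(x)
}

#' @export
as.data.frame.gtm_selection <- function(x, ...) {
  rows <- lapply(x$steps, function(st) {
    others <- st$scores[names(st$scores) != st$chosen]
    ru <- if (length(others)) names(others)[which.max(others)] else NA_character_
    data.frame(step = st$step, chosen = st$chosen, score = st$score,
               runner_up = ru,
               runner_up_score = if (is.na(ru)) NA_real_ else max(others),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a selection trace to CSV
#'
#' Columns: `step`, `chosen`, `score`, `runner_up`, `runner_up_score`.
#'
#' @param trace a `"gtm_selection"` object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "gtm_selection"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a selection trace (with full per-step score maps) to JSON
#'
#' @inheritParams write_trace_csv
#' @return The path, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "gtm_selection"))
  out <- list(criterion = trace$criterion, selected = trace$selected,
              stopped_early = trace$stopped_early,
              steps = lapply(trace$steps, function(st) {
                list(step = st$step, chosen = st$chosen, score = st$score,
                     scores = as.list(st$scores))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Smallest k at which JMI prefers the inactive child
#'
#' For `0 < gamma < 1`, finds the minimal `k >= 1` such that, with
#' `S = {X1..Xk}` selected, `JMI(X_{k+1} | X_S) < JMI(X1(1) | X_S)` — the
#' point at which greedy JMI selection starts to pick the non-Markov-blanket
#' child before the remaining active predictor. The crossover is guaranteed
#' finite for `gamma < 1` (the active score vanishes with `k` while the
#' child score does not); the search is bounded by
#' `10 * ceiling(-log(2) / (2 log gamma)) + 50` and errors if exceeded.
#' At `gamma = 1` no crossover exists, and the function refuses the input.
#'
#' @param gamma decay parameter in (0, 1).
#' @param cfg a [quad_config()].
#' @return The minimal `k`, an integer.
#' @examples
#' jmi_crossover_k(2/3) # 2
#' @export
jmi_crossover_k <- function(gamma, cfg = quad_config()) {
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0 || gamma >= 1) {
    stop("'gamma' must lie strictly inside (0, 1); at gamma = 1 JMI never ",
         "prefers the child")
  }
  bound <- 10 * ceiling(-log(2) / (2 * log(gamma))) + 50
  for (k in seq_len(bound)) {
    spec <- gtm_spec(k, gamma)
    if (gtm_jmi_closed(spec, "active", cfg) <
        gtm_jmi_closed(spec, "child", cfg)) {
      return(k)
    }
  }
  stop("no JMI crossover found up to k = ", bound,
       "; this contradicts the asymptotic argument")
}

#' CIFE crossover at gamma = 1
#'
#' At `gamma = 1` both CIFE scores (for the last active `X_{k+1}` and for the
#' child `X1(1)`, given `S = {X1..Xk}`) are affine, decreasing functions of
#' `k`. The active score decreases faster, so for sufficiently large `k` CIFE
#' ranks the inactive child above the remaining active predictor. This
#' function returns the smallest such `k`.
#'
#' @param cfg a [quad_config()].
#' @return The minimal `k` with
#'   `CIFE(X_{k+1} | X_S) < CIFE(X1(1) | X_S)`, an integer.
#' @export
cife_gamma1_crossover_k <- function(cfg = quad_config()) {
  for (k in seq_len(1000)) {
    spec <- gtm_spec(k, 1)
    if (gtm_cife_closed(spec, "active", cfg) <
        gtm_cife_closed(spec, "child", cfg)) {
      return(k)
    }
  }
  stop("no CIFE crossover found up to k = 1000")
}

#' Positive selection rate
#'
#' Fraction of the Markov blanket `{X1, ..., X_{k+1}}` recovered by a
#' selection: `|selected ∩ blanket| / |blanket|`. The child `X1(1)` never
#' counts toward the rate.
#'
#' @param selected character vector of selected variable labels (or a
#'   `"gtm_selection"` trace, whose `selected` field is used).
#' @param spec a [gtm_spec()].
#' @return A value in `[0, 1]`.
#' @examples
#' psr(c("X1", "X2", "X1(1)"), gtm_spec(2, 1)) # 2/3
#' @export
psr <- function(selected, spec) {
  stopifnot(inherits(spec, "gtm_spec"))
  if (inherits(selected, "gtm_selection")) selected <- selected$selected
  .active_index(spec, selected)
  blanket <- paste0("X", seq_len(spec$k + 1))
  mean(blanket %in% selected)
}
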