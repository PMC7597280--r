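# Printed-table convention: values within 1e-9 of zero are reported as 0
# (avoids "-0.0000" entries), then rounded to 4 decimals.
.round4 <- function(x) {
  x[abs(x) < 1e-9] <- 0
  round(x, 4)
}

#' Criterion table for one model: the three-panel comparison
#'
#' Runs greedy forward selection under each requested criterion for the full
#' `k + 2` steps and collects, for every step, the scores of all remaining
#' candidates given that criterion's own selected set so far. For the default
#' `M(2, 2/3)` this reproduces the canonical three-panel comparison in which
#' CMI ranks the Markov blanket first, JMI erroneously promotes the child
#' `X1(1)` at step 3, and CIFE keeps the correct order but goes negative for
#' the child.
#'
#' @param spec a [gtm_spec()]; defaults to `M(2, 2/3)`.
#' @param criteria character vector of criteria to tabulate.
#' @param cfg a [quad_config()].
#' @return A data frame with columns `criterion`, `step`, `conditioning_set`
#'   (semicolon-joined, `""` for the first step), `candidate`, `value_nats`
#'   (full precision), `value_rounded` (4 decimals, as conventionally
#'   printed), `value_bits`, and `chosen`.
#' @examples
#' t1 <- gtm_table1()
#' subset(t1, criterion == "jmi" & step == 3)
#' @export
gtm_table1 <- function(spec = gtm_spec(2, 2/3),
                       criteria = c("cmi", "jmi", "cife"),
                       cfg = quad_config()) {
  stopifnot(inherits(spec, "gtm_spec"))
  rows <- list()
  for (crit in criteria) {
    trace <- greedy_select(spec, crit, n_steps = spec$k + 2, cfg = cfg)
    sel <- character(0)
    for (st in trace$steps) {
      rows[[length(rows) + 1]] <- data.frame(
        criterion = crit, step = st$step,
        conditioning_set = paste(sel, collapse = ";"),
        candidate = names(st$scores),
        value_nats = unname(st$scores),
        value_rounded = .round4(unname(st$scores)),
        value_bits = nats_to_bits(unname(st$scores)),
        chosen = names(st$scores) == st$chosen,
        stringsAsFactors = FALSE)
      sel <- c(sel, st$chosen)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a criterion table to CSV
#'
#' Columns `criterion`, `candidate`, `conditioning_set`, `value_nats`,
#' `value_bits` (plus any others present in `df`), in a deterministic order.
#'
#' @param df a data frame from [gtm_table1()] or a compatible one.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_criteria_csv <- function(df, path) {
  lead <- intersect(c("criterion", "candidate", "conditioning_set",
                      "value_nats", "value_bits"), names(df))
  df <- df[c(lead, setdiff(names(df), lead))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' CMI of the last active predictor as a function of k
#'
#' Tabulates `g(k, gamma) = I(X_{k+1}, Y | X_1..X_k)` over `k = 1..k_max` for
#' each `gamma`, via [gtm_cmi_closed()]. The value is strictly positive for
#' every `k` (the last active always carries fresh information) and strictly
#' decreasing in `k`.
#'
#' @param gammas numeric vector of decay parameters in (0, 1].
#' @param k_max largest `k`.
#' @param cfg a [quad_config()].
#' @return Data frame with columns `gamma`, `k`, `value`.
#' @export
cmi_curve <- function(gammas = c(0.3, 0.5, 2/3, 0.8, 1), k_max = 12,
                      cfg = quad_config()) {
  grid <- expand.grid(k = seq_len(k_max), gamma = gammas)
  grid$value <- mapply(function(k, g) gtm_cmi_closed(gtm_spec(k, g), cfg),
                       grid$k, grid$gamma)
  grid[c("gamma", "k", "value")]
}

#' JMI crossover table
#'
#' Minimal `k` at which JMI prefers the inactive child, per `gamma`
#' (see [jmi_crossover_k()]).
#'
#' @param gammas numeric vector of decay parameters strictly inside (0, 1).
#' @param cfg a [quad_config()].
#' @return Data frame with columns `gamma`, `minimal_k`.
#' @export
jmi_crossover_table <- function(gammas = seq(0.1, 0.9, by = 0.1),
                                cfg = quad_config()) {
  data.frame(gamma = gammas,
             minimal_k = vapply(gammas, jmi_crossover_k, integer(1), cfg = cfg))
}

#' Active-versus-child criterion score curves
#'
#' For each criterion (JMI and CIFE), `gamma` and `k`, the closed-form scores
#' of the last active `X_{k+1}` and of the child `X1(1)` given
#' `S = {X1..Xk}`, and their difference (positive means the active predictor
#' is preferred). JMI differences dip below zero for `gamma < 1` once `k`
#' passes the crossover; CIFE differences go negative only at `gamma = 1`.
#'
#' @param gammas numeric vector of decay parameters in (0, 1].
#' @param k_max largest `k`.
#' @param cfg a [quad_config()].
#' @return Data frame with columns `criterion`, `gamma`, `k`, `score_active`,
#'   `score_child`, `difference`.
#' @export
criterion_curves <- function(gammas = c(0.5, 2/3, 0.8, 0.9, 1), k_max = 30,
                             cfg = quad_config()) {
  grid <- expand.grid(k = seq_len(k_max), gamma = gammas,
                      criterion = c("jmi", "cife"),
                      stringsAsFactors = FALSE)
  closed <- function(crit, k, g, cand) {
    spec <- gtm_spec(k, g)
    if (crit == "jmi") gtm_jmi_closed(spec, cand, cfg)
    else gtm_cife_closed(spec, cand, cfg)
  }
  grid$score_active <- mapply(closed, grid$criterion, grid$k, grid$gamma,
                              MoreArgs = list(cand = "active"))
  grid$score_child <- mapply(closed, grid$criterion, grid$k, grid$gamma,
                             MoreArgs = list(cand = "child"))
  grid$difference <- grid$score_active - grid$score_child
  grid[c("criterion", "gamma", "k", "score_active", "score_child",
         "difference")]
}
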