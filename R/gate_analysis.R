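# Logic-gate evaluation of multi-input hybrid promoters.
#
# An n-input transcriptional AND gate should transcribe if and only if the
# cognate inducers of all n transcription factors are present. Gates are
# scored from complete truth tables (2^n inducer on/off combinations) on
# replicate means.

#' Enumerate all inducer on/off combinations
#'
#' Builds the 2^k truth-table conditions for k input ligands, each ligand at
#' 0 or its working concentration, in canonical binary order: all-off first,
#' all-on last, first input as the most significant bit.
#'
#' @param inputs Character vector of ligand names (the gate inputs).
#' @param working_concentrations Named concentrations; defaults to
#'   [default_working_concentrations()].
#' @return Named list of [inducer_condition()]s; names are binary strings
#'   (e.g. `"101"`).
#' @examples
#' names(enumerate_conditions(c("arabinose", "IPTG")))
#' @export
enumerate_conditions <- function(inputs,
                                 working_concentrations = default_working_concentrations()) {
  if (length(inputs) == 0L)
    return(stats::setNames(list(inducer_condition()), ""))
  miss <- setdiff(inputs, names(working_concentrations))
  if (length(miss))
    stop("no working concentration for input(s): ", paste(miss, collapse = ", "))
  wc <- working_concentrations[inputs]
  if (any(wc <= 0)) stop("working concentrations must be > 0")
  k <- length(inputs)
  out <- list()
  for (i in 0:(2^k - 1L)) {
    bits <- as.integer(intToBits(i))[k:1]  # first input = most significant
    conc <- wc * bits
    out[[paste(bits, collapse = "")]] <-
      as_condition(stats::setNames(as.numeric(conc), inputs))
  }
  out
}

#' Build a truth table from measurements
#'
#' Aggregates replicate measurements of one promoter into a complete truth
#' table over the gate inputs. Rows are matched to input states through the
#' condition definitions: a ligand is "on" in a condition iff its
#' concentration is positive.
#'
#' @param data Data frame with columns `condition` and a rate column
#'   (`rate_rpu` or `rpu`); typically one promoter's rows of an observation
#'   table or [normalize_plate()] output.
#' @param inputs Character vector of ligand names, in display order.
#' @param conditions Named list of [inducer_condition()]s keyed by the
#'   condition ids in `data` (default: ids are themselves binary strings
#'   over `inputs`, as produced by [enumerate_conditions()]).
#' @return Data frame of class `truth_table`: one column per input (0/1),
#'   plus `mean`, `sd`, `n`; attribute `"inputs"`.
#' @export
truth_table <- function(data, inputs, conditions = NULL) {
  rate_col <- intersect(c("rate_rpu", "rpu"), names(data))[1L]
  if (is.na(rate_col)) stop("'data' needs a rate_rpu or rpu column")
  ids <- unique(data$condition)
  if (is.null(conditions)) {
    if (!all(grepl("^[01]+$", ids)) || !all(nchar(ids) == length(inputs)))
      stop("condition ids are not binary strings over the inputs; ",
           "supply 'conditions' explicitly")
    states <- do.call(rbind, lapply(strsplit(ids, ""), as.integer))
  } else {
    miss <- setdiff(ids, names(conditions))
    if (length(miss)) stop("no condition definition for: ", paste(miss, collapse = ", "))
    states <- t(vapply(conditions[ids], function(cond)
      as.integer(inputs %in% names(cond)[cond > 0]), integer(length(inputs))))
  }
  colnames(states) <- inputs
  key <- apply(states, 1L, paste, collapse = "")
  if (anyDuplicated(key))
    stop("multiple condition ids map to the same input state")

  rows <- lapply(seq_along(ids), function(i) {
    x <- data[data$condition == ids[i], rate_col]
    cbind(as.data.frame(t(states[i, , drop = TRUE])),
          mean = mean(x),
          sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
          n = length(x))
  })
  tt <- do.call(rbind, rows)
  tt <- tt[order(apply(tt[, inputs, drop = FALSE], 1L, paste, collapse = "")), ,
           drop = FALSE]
  rownames(tt) <- NULL
  attr(tt, "inputs") <- inputs
  class(tt) <- c("truth_table", "data.frame")
  tt
}

#' Score a promoter as an AND gate
#'
#' From a complete truth table: `signal` (the all-inducers-present rate),
#' `leakiness` (the maximum rate over every other state), their ratio
#' `and_score` and difference `dynamic_range`.
#'
#' @param table A [truth_table()] covering all 2^k input states.
#' @return List of class `gate_metrics` with elements `on_rate`,
#'   `max_off_rate`, `leakiness`, `signal`, `and_score`, `dynamic_range`.
#' @export
gate_metrics <- function(table) {
  stopifnot(inherits(table, "truth_table"))
  inputs <- attr(table, "inputs")
  states <- as.matrix(table[, inputs, drop = FALSE])
  want <- apply(expand.grid(rep(list(0:1), length(inputs))), 1L, paste,
                collapse = "")
  have <- apply(states, 1L, paste, collapse = "")
  miss <- setdiff(want, have)
  if (length(miss))
    stop("incomplete truth table; missing state(s): ",
         paste(miss, collapse = ", "))
  on_row <- rowSums(states) == length(inputs)
  on_rate <- table$mean[on_row]
  max_off <- max(table$mean[!on_row])
  structure(list(on_rate = on_rate, max_off_rate = max_off,
                 leakiness = max_off, signal = on_rate,
                 and_score = on_rate / max_off,
                 dynamic_range = on_rate - max_off),
            class = "gate_metrics")
}

#' @export
print.gate_metrics <- function(x, ...) {
  cat(sprintf(
    "<gate_metrics> signal = %.4g, leakiness = %.4g, AND score = %.3g, dynamic range = %.4g\n",
    x$signal, x$leakiness, x$and_score, x$dynamic_range))
  invisible(x)
}

#' Is a gate a well-behaved AND gate?
#'
#' `TRUE` iff the promoter is at least `min_score`-fold more active with all
#' inducers present than in any other state (boundary inclusive).
#'
#' @param metrics A [gate_metrics()] result.
#' @param min_score Required ON/OFF ratio; must be > 1 (default 10).
#' @return Logical.
#' @export
is_well_behaved_and <- function(metrics, min_score = 10) {
  stopifnot(inherits(metrics, "gate_metrics"))
  if (!is.numeric(min_score) || min_score <= 1) stop("'min_score' must be > 1")
  metrics$and_score >= min_score
}

#' Classify a promoter's leak/signal phenotype
#'
#' Partitions the (leakiness, signal) plane into the four quadrant
#' phenotypes: strictly below a threshold counts as "low". The weakest
#' library members are low-leak/low-signal (bD-like), the strongest
#' high-leak/high-signal (eG-like), and the prized gate parts
#' low-leak/high-signal (dE/dF-like).
#'
#' @param leak,signal Observed OFF-state and ON-state rates (RPU).
#' @param leak_threshold,signal_threshold Positive classification
#'   thresholds.
#' @return List of class `phenotype_class` with `label` and `thresholds`.
#' @export
classify_phenotype <- function(leak, signal, leak_threshold, signal_threshold) {
  if (leak_threshold <= 0 || signal_threshold <= 0)
    stop("thresholds must be > 0")
  label <- paste0(if (leak < leak_threshold) "low-leak" else "high-leak", "/",
                  if (signal < signal_threshold) "low-signal" else "high-signal")
  structure(list(label = label,
                 thresholds = c(leak = leak_threshold, signal = signal_threshold)),
            class = "phenotype_class")
}

#' Default phenotype thresholds from a library's leak/signal distribution
#'
#' The geometric midpoint of the observed range of each axis.
#'
#' @param leaks,signals Positive rate vectors across a library.
#' @return Named vector with `leak` and `signal` thresholds.
#' @export
phenotype_thresholds <- function(leaks, signals) {
  stopifnot(all(leaks > 0), all(signals > 0))
  c(leak = exp(mean(range(log(leaks)))),
    signal = exp(mean(range(log(signals)))))
}

#' Rank -35 x -10 combinations for gate construction
#'
#' Orders every fitted combination by a design objective between an OFF and
#' an ON condition, descending; ties broken by fold change, then
#' lexicographically by (-35, -10) label.
#'
#' @param fit A `promoter_fit` covering the library.
#' @param off,on [inducer_condition()]s.
#' @param objective `"dynamic_range"`, `"fold_change"` or `"and_score"`
#'   (for a two-condition comparison the AND score is the ON/OFF ratio).
#' @return Data frame with columns `minus35`, `minus10`, `score`,
#'   `fold_change`, `r_off`, `r_on`, best first.
#' @export
rank_combinations <- function(fit, off, on,
                              objective = c("dynamic_range", "fold_change",
                                            "and_score")) {
  stopifnot(inherits(fit, "promoter_fit"))
  objective <- match.arg(objective)
  v <- fit$variants
  r_off <- numeric(nrow(v)); r_on <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    p <- fit_params_for(fit, v$minus35[i], v$minus10[i])
    r_off[i] <- transcription_rate(p, off)
    r_on[i] <- transcription_rate(p, on)
  }
  fc <- r_on / r_off
  score <- switch(objective,
                  dynamic_range = r_on - r_off,
                  fold_change = fc,
                  and_score = r_on / r_off)
  out <- data.frame(minus35 = v$minus35, minus10 = v$minus10, score = score,
                    fold_change = fc, r_off = r_off, r_on = r_on,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$fold_change, out$minus35, out$minus10), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
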