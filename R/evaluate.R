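#' Compare pipeline verdicts with simulation ground truth
#'
#' Maps each pipeline group to a true species by majority vote over its
#' member samples, takes the verdict between the primary (largest) group
#' of each species pair, and scores the predicted decisions against the
#' expected ones. Precision and recall are computed for the
#' `distinct_species` class, the one that defines species boundaries.
#'
#' @param result a [run_pipeline()] result.
#' @param truth a truth record ([read_truth()] or
#'   `simulate_dataset()$truth`).
#' @return A list with `pairs` (data.frame: expected vs predicted decision
#'   and introgression flags per species pair), `precision`, `recall` and
#'   `accuracy` (proportion of pairs with exactly matching decisions).
#' @export
evaluate_against_truth <- function(result, truth) {
  stopifnot(inherits(result, "delimitation_result"))
  species_of <- truth$samples
  asg <- result$assignments
  asg$species <- species_of[asg$sample_id]
  # majority species per group; primary group per species = largest
  grp_species <- vapply(split(asg$species, asg$group_id), function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    names(sort(table(x), decreasing = TRUE))[1L]
  }, "")
  primary <- vapply(split(asg, grp_species[asg$group_id]), function(d) {
    names(sort(table(d$group_id), decreasing = TRUE))[1L]
  }, "")
  tp <- truth$pairs
  pred_dec <- character(nrow(tp))
  pred_flag <- logical(nrow(tp))
  v <- result$verdicts
  for (i in seq_len(nrow(tp))) {
    if (!tp$group_a[i] %in% names(primary) ||
        !tp$group_b[i] %in% names(primary)) {
      pred_dec[i] <- "unresolved"
      next
    }
    ga <- primary[[tp$group_a[i]]]
    gb <- primary[[tp$group_b[i]]]
    if (ga == gb) {
      # the pipeline merged the two species into one group
      pred_dec[i] <- "merged"
      next
    }
    row <- v[(v$group_a == ga & v$group_b == gb) |
               (v$group_a == gb & v$group_b == ga), , drop = FALSE]
    if (nrow(row) == 1L) {
      pred_dec[i] <- row$decision
      pred_flag[i] <- row$introgression_flag
    } else {
      pred_dec[i] <- "unresolved"
    }
  }
  pairs <- data.frame(
    group_a = tp$group_a, group_b = tp$group_b,
    expected = tp$decision, predicted = pred_dec,
    expected_flag = tp$introgression_flag, predicted_flag = pred_flag,
    stringsAsFactors = FALSE
  )
  pos_true <- pairs$expected == "distinct_species"
  pos_pred <- pairs$predicted == "distinct_species"
  tp_n <- sum(pos_true & pos_pred)
  precision <- if (sum(pos_pred)) tp_n / sum(pos_pred) else NA_real_
  recall <- if (sum(pos_true)) tp_n / sum(pos_true) else NA_real_
  list(pairs = pairs, precision = precision, recall = recall,
       accuracy = mean(pairs$expected == pairs$predicted))
}
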