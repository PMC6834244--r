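#' Guideline maximum daily doses
#'
#' Maximum daily doses (mg) recommended by European guidelines for the
#' beta-blockers and ACE-inhibitors / angiotensin-receptor blockers
#' handled by the titration engine. Ladders for these agents must top out
#' exactly at these values.
#'
#' @format named numeric vector, mg per day.
#' @export
guideline_max_daily <- c(
  perindopril = 10, enalapril = 10, ramipril = 10, lisinopril = 20,
  candesartan = 16, losartan = 100,
  bisoprolol = 10, nebivolol = 5
)

#' A per-drug dose ladder
#'
#' The ordered sequence of permitted daily doses for one agent, ending at
#' the guideline-recommended maximum. Uptitration moves exactly one step
#' up the ladder; the top step is a hard safety cap.
#'
#' @param drug_name agent name (lower case), e.g. `"bisoprolol"`.
#' @param drug_class `"beta_blocker"` or `"ace_i"` (the ACE-I class also
#'   covers angiotensin-receptor blockers).
#' @param steps strictly increasing daily doses in mg; the last step is
#'   the guideline maximum.
#' @return an object of class `dose_ladder`.
#' @export
#' @examples
#' dose_ladder("bisoprolol", "beta_blocker", c(1.25, 2.5, 3.75, 5, 7.5, 10))
dose_ladder <- function(drug_name, drug_class = c("beta_blocker", "ace_i"),
                        steps) {
  drug_class <- match.arg(drug_class)
  steps <- as.numeric(steps)
  assert_that(length(steps) >= 1 && all(steps > 0) &&
                all(diff(steps) > 0), "steps must be strictly increasing and positive")
  max_daily <- steps[length(steps)]
  known <- guideline_max_daily[[tolower(drug_name)]] %||% NULL
  if (!is.null(known)) {
    assert_that(isTRUE(all.equal(max_daily, known)),
                sprintf("%s ladder must top out at the guideline maximum of %g mg",
                        drug_name, known))
  }
  structure(list(drug_name = tolower(drug_name), drug_class = drug_class,
                 steps = steps, max_daily = max_daily),
            class = "dose_ladder")
}

#' @export
print.dose_ladder <- function(x, ...) {
  cat(sprintf("<dose_ladder> %s (%s): %s mg (max %g)\n", x$drug_name,
              x$drug_class, paste(x$steps, collapse = "/"), x$max_daily))
  invisible(x)
}

#' Default dose ladders
#'
#' Ladders for the agents the engine knows about. The guideline fixes
#' only the maxima; intermediate steps follow common European titration
#' practice (start low, roughly double toward the maximum).
#'
#' @return named list of [dose_ladder()] objects.
#' @export
default_ladders <- function() {
  list(
    bisoprolol  = dose_ladder("bisoprolol", "beta_blocker",
                              c(1.25, 2.5, 3.75, 5, 7.5, 10)),
    nebivolol   = dose_ladder("nebivolol", "beta_blocker", c(1.25, 2.5, 5)),
    enalapril   = dose_ladder("enalapril", "ace_i", c(2.5, 5, 10)),
    ramipril    = dose_ladder("ramipril", "ace_i", c(1.25, 2.5, 5, 10)),
    perindopril = dose_ladder("perindopril", "ace_i", c(2.5, 5, 10)),
    lisinopril  = dose_ladder("lisinopril", "ace_i", c(2.5, 5, 10, 20)),
    candesartan = dose_ladder("candesartan", "ace_i", c(4, 8, 16)),
    losartan    = dose_ladder("losartan", "ace_i", c(25, 50, 100))
  )
}

#' A patient's medication plan
#'
#' Tracks the patient's current position on one beta-blocker ladder and
#' one ACE-I ladder, plus an optional diuretic whose adherence is
#' monitored but which the engine never titrates.
#'
#' @param patient_id patient identifier.
#' @param beta_blocker a [dose_ladder()] of class `beta_blocker`.
#' @param ace_i a [dose_ladder()] of class `ace_i`.
#' @param bb_step,ace_step current 1-based step index on each ladder.
#' @param diuretic logical: is a (monitored-only) diuretic part of the
#'   scheme?
#' @return an object of class `medication_plan`.
#' @export
medication_plan <- function(patient_id,
                            beta_blocker = default_ladders()$bisoprolol,
                            ace_i = default_ladders()$enalapril,
                            bb_step = 1L, ace_step = 1L, diuretic = TRUE) {
  assert_that(inherits(beta_blocker, "dose_ladder") &&
                beta_blocker$drug_class == "beta_blocker",
              "beta_blocker must be a beta-blocker dose_ladder")
  assert_that(inherits(ace_i, "dose_ladder") && ace_i$drug_class == "ace_i",
              "ace_i must be an ACE-I dose_ladder")
  assert_that(bb_step >= 1 && bb_step <= length(beta_blocker$steps),
              "bb_step outside ladder")
  assert_that(ace_step >= 1 && ace_step <= length(ace_i$steps),
              "ace_step outside ladder")
  structure(
    list(patient_id = as.character(patient_id),
         drugs = list(
           beta_blocker = list(ladder = beta_blocker,
                               current_step_index = as.integer(bb_step),
                               at_optimal = FALSE),
           ace_i = list(ladder = ace_i,
                        current_step_index = as.integer(ace_step),
                        at_optimal = FALSE)),
         diuretic = isTRUE(diuretic)),
    class = "medication_plan")
}

#' @export
print.medication_plan <- function(x, ...) {
  cat(sprintf("<medication_plan> patient %s\n", x$patient_id))
  for (cls in names(x$drugs)) {
    d <- x$drugs[[cls]]
    cat(sprintf("  %s: %s %g mg (step %d/%d)%s\n", cls, d$ladder$drug_name,
                current_dose(x, cls), d$current_step_index,
                length(d$ladder$steps),
                if (d$at_optimal) " [optimal reached]" else ""))
  }
  if (x$diuretic) cat("  diuretic: monitored only\n")
  invisible(x)
}

#' Current daily dose for a drug class
#'
#' @param plan a [medication_plan()].
#' @param drug_class `"beta_blocker"` or `"ace_i"`.
#' @return daily dose in mg.
#' @export
current_dose <- function(plan, drug_class = c("beta_blocker", "ace_i")) {
  drug_class <- match.arg(drug_class)
  d <- plan$drugs[[drug_class]]
  d$ladder$steps[[d$current_step_index]]
}

at_top_step <- function(plan, drug_class) {
  d <- plan$drugs[[drug_class]]
  d$current_step_index >= length(d$ladder$steps)
}
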