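#' Canonical vital-rate submodel table
#'
#' The study design models eleven binomial vital-rate submodels across six
#' age-sex classes: August-to-August survival of female/male lambs,
#' yearlings and adults (6), spring reproduction of ewes in each age class
#' (3), and twinning of yearling and adult ewes (2). Survival submodels
#' other than male lamb survival respond to the first environmental axis
#' through a piecewise (threshold) linear predictor; the fecundity
#' submodels and male lamb survival are plain logistic. Lamb reproduction,
#' adult reproduction and adult twinning additionally load on the second
#' environmental axis.
#'
#' @return A data frame with one row per submodel and columns `id`, `name`,
#'   `process` (`"survival"`, `"reproduction"` or `"twinning"`),
#'   `age_class`, `sex`, `thresholded` (logical) and `second_axis`
#'   (logical).
#' @examples
#' soay_submodels()
#' @export
soay_submodels <- function() {
  data.frame(
    id = 1:11,
    name = c("surv.lamb.F", "surv.lamb.M", "surv.yrl.F", "surv.yrl.M",
             "surv.ad.F", "surv.ad.M",
             "repro.lamb", "repro.yrl", "repro.ad",
             "twin.yrl", "twin.ad"),
    process = c(rep("survival", 6), rep("reproduction", 3), rep("twinning", 2)),
    age_class = c("lamb", "lamb", "yearling", "yearling", "adult", "adult",
                  "lamb", "yearling", "adult", "yearling", "adult"),
    sex = c("F", "M", "F", "M", "F", "M", rep("F", 5)),
    thresholded = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, rep(FALSE, 5)),
    second_axis = c(rep(FALSE, 6), TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Validate a submodel table
#'
#' Checks structural requirements on a submodel table. With
#' `canonical = TRUE` the full study-design composition is enforced:
#' exactly six survival, three reproduction and two twinning submodels;
#' thresholds on precisely the five survival submodels other than male lamb
#' survival; and second-axis loadings on exactly lamb reproduction, adult
#' reproduction and adult twinning. Non-canonical tables (used for reduced
#' toy models in tests and conjugate checks) only need consistent columns.
#'
#' @param submodels A data frame as returned by [soay_submodels()].
#' @param canonical Enforce the full 11-submodel study design?
#' @return `submodels`, invisibly, after validation.
#' @export
validate_submodels <- function(submodels, canonical = FALSE) {
  need <- c("id", "name", "process", "age_class", "sex", "thresholded", "second_axis")
  if (!all(need %in% names(submodels)))
    stop("submodel table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(submodels$name))
    stop("submodel names must be unique")
  if (!all(submodels$process %in% c("survival", "reproduction", "twinning")))
    stop("unknown process in submodel table")
  if (any(submodels$thresholded & submodels$process != "survival"))
    stop("only survival submodels may be thresholded")
  if (canonical) {
    cnt <- table(factor(submodels$process,
                        levels = c("survival", "reproduction", "twinning")))
    if (!identical(as.integer(cnt), c(6L, 3L, 2L)))
      stop("canonical design requires 6 survival, 3 reproduction, 2 twinning submodels")
    thr_expect <- submodels$process == "survival" &
      !(submodels$age_class == "lamb" & submodels$sex == "M")
    if (!identical(submodels$thresholded, thr_expect))
      stop("canonical design thresholds all survival submodels except male lamb survival")
    sa_expect <- submodels$name %in% c("repro.lamb", "repro.ad", "twin.ad")
    if (!identical(submodels$second_axis, sa_expect))
      stop("canonical second axis loads on lamb reproduction, adult reproduction and adult twinning")
  }
  invisible(submodels)
}
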