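#' Damage level labels
#'
#' The four-level defoliation grading used throughout the package:
#' 1 = Healthy, 2 = Mild, 3 = Moderate, 4 = Severe.
#'
#' @return Character vector of the four level names, in order.
#' @export
damage_levels <- function() c("Healthy", "Mild", "Moderate", "Severe")

# Leaf-loss-rate bands (percent) defining the four levels. Upper edges are
# inclusive so the printed integer bands (0-5, 6-30, 31-70, 71-100) keep
# their membership while fractional rates are covered by half-open bands.
.level_upper <- c(5, 30, 70, 100)

#' Leaf-loss-rate band for each damage level
#'
#' @return A 4x2 matrix with columns `lower` and `upper` (percent). A tree
#'   with leaf-loss rate DR belongs to level `k` when
#'   `lower[k] < DR <= upper[k]` (level 1 additionally includes DR = 0).
#' @export
level_bands <- function() {
  cbind(lower = c(0, .level_upper[-4]), upper = .level_upper)
}

#' Leaf-loss rate from needle counts
#'
#' The defoliation measure: the percentage of damaged needles among all
#' needles counted on a tree, `100 * L_d / (L_h + L_d)`.
#'
#' @param L_h Healthy-needle count(s), non-negative.
#' @param L_d Damaged-needle count(s), non-negative.
#' @return Leaf-loss rate in percent, in \[0, 100\]. Vectorised.
#' @examples
#' leaf_loss_rate(30, 10)  # 25
#' @export
leaf_loss_rate <- function(L_h, L_d) {
  if (any(L_h < 0) || any(L_d < 0))
    stop("needle counts must be non-negative")
  tot <- L_h + L_d
  if (any(tot <= 0))
    stop("total needle count must be positive")
  100 * L_d / tot
}

#' Assign a damage level from the leaf-loss rate
#'
#' Healthy for DR <= 5, Mild for 5 < DR <= 30, Moderate for 30 < DR <= 70,
#' Severe for DR > 70.
#'
#' @param DR Leaf-loss rate(s) in percent, in \[0, 100\].
#' @return Integer vector of levels in 1..4 with a `"damage_level"` factor
#'   attached via [level_name()] semantics.
#' @export
classify_level <- function(DR) {
  if (any(!is.finite(DR)) || any(DR < 0) || any(DR > 100))
    stop("DR must be within [0, 100]")
  findInterval(DR, .level_upper, left.open = TRUE) + 1L
}

#' Name of a damage level
#'
#' @param level Integer level(s) in 1..4.
#' @return Factor with levels Healthy < Mild < Moderate < Severe.
#' @export
level_name <- function(level) {
  stopifnot(all(level %in% 1:4))
  factor(damage_levels()[level], levels = damage_levels(), ordered = TRUE)
}

#' Tree-level leaf-loss rate from branch rates
#'
#' Field surveys count needles on several branches per tree (three per
#' crown layer); the tree's rate is the arithmetic mean of the branch rates.
#'
#' @param branch_rates Numeric vector of per-branch leaf-loss rates
#'   in percent.
#' @return Mean rate in percent.
#' @export
aggregate_branches <- function(branch_rates) {
  if (length(branch_rates) == 0)
    stop("branch_rates must be non-empty")
  if (any(!is.finite(branch_rates)) || any(branch_rates < 0) ||
      any(branch_rates > 100))
    stop("branch rates must be within [0, 100]")
  mean(branch_rates)
}

#' Build survey records from needle counts
#'
#' @param tree_id Identifier per tree.
#' @param L_h,L_d Healthy and damaged needle counts.
#' @return A `data.frame` with columns `tree_id`, `L_h`, `L_d`, `DR`
#'   (percent) and `level` (integer 1..4).
#' @export
survey_records <- function(tree_id, L_h, L_d) {
  DR <- leaf_loss_rate(L_h, L_d)
  data.frame(tree_id = tree_id, L_h = L_h, L_d = L_d, DR = DR,
             level = classify_level(DR))
}

#' Read / write a survey table
#'
#' Plain-CSV persistence of survey records with columns
#' `tree_id,healthy_needles,damaged_needles,DR,level`.
#'
#' @param survey A survey `data.frame` as from [survey_records()].
#' @param path File path.
#' @return `read_survey` returns the survey `data.frame`;
#'   `write_survey` returns `path` invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- data.frame(tree_id = survey$tree_id,
                    healthy_needles = survey$L_h,
                    damaged_needles = survey$L_d,
                    DR = survey$DR, level = survey$level)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  raw <- utils::read.csv(path)
  survey_records(raw$tree_id, raw$healthy_needles, raw$damaged_needles)
}
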