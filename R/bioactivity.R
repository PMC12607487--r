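#' Percent enzyme inhibition from absorbances
#'
#' \%Inhibition = (A_control - A_sample) / A_control x 100. Negative values
#' indicate activation and are returned as-is.
#'
#' @param a_control control absorbance (> 0).
#' @param a_sample sample absorbance.
#' @return percent inhibition (vectorized).
#' @export
#' @examples
#' percent_inhibition(1.0, 0.5) # 50
percent_inhibition <- function(a_control, a_sample) {
  if (any(a_control <= 0)) stop("a_control must be positive", call. = FALSE)
  (a_control - a_sample) / a_control * 100
}

#' Percent improvement of a combination over a single agent
#'
#' In \code{"plain"} mode (inhibition percentages) the improvement is
#' (combined - single)/single x 100. In \code{"magnitude"} mode (docking
#' scores, where more negative means stronger binding) the formula is
#' applied to absolute values, (|combined| - |single|)/|single| x 100.
#' Report columns round half away from zero to integers; the unrounded
#' value is what this function returns unless \code{rounded = TRUE}.
#'
#' @param combined readout of the two-agent combination.
#' @param single readout of the reference single agent (nonzero).
#' @param mode \code{"plain"} or \code{"magnitude"}.
#' @param rounded return the integer-rounded report value.
#' @return percent improvement (vectorized).
#' @export
#' @examples
#' improvement_pct(89.76, 40.97, rounded = TRUE)              # 119
#' improvement_pct(-10.03, -5.26, "magnitude", rounded = TRUE) # 91
improvement_pct <- function(combined, single,
                            mode = c("plain", "magnitude"),
                            rounded = FALSE) {
  mode <- match.arg(mode)
  if (any(single == 0)) stop("'single' must be nonzero", call. = FALSE)
  out <- if (mode == "plain") {
    (combined - single) / single * 100
  } else {
    (abs(combined) - abs(single)) / abs(single) * 100
  }
  if (rounded) round_half_away(out) else out
}

#' Build a synergy table from single-agent and combination records
#'
#' For every pairwise combination, computes the percent improvement
#' relative to each of its two single agents (both reference directions
#' are always reported, keyed explicitly by reference agent rather than by
#' printing position). Raw improvements are kept at full precision; the
#' \code{improvement_rounded} column holds the integer report values.
#'
#' @param singles single-agent values: a data.frame with columns
#'   \code{agent, value}, or a named numeric vector.
#' @param combos pairwise values: a data.frame with columns
#'   \code{agent_a, agent_b, value}.
#' @param mode \code{"plain"} for inhibition percentages,
#'   \code{"magnitude"} for docking scores (see
#'   \code{\link{improvement_pct}}).
#' @return an object of class \code{synergy_table} with elements
#'   \code{singles} (named vector), \code{combos} (data.frame), and
#'   \code{improvements} (data.frame with one row per combination x
#'   reference agent).
#' @export
build_synergy_table <- function(singles, combos, mode = c("plain", "magnitude")) {
  mode <- match.arg(mode)
  if (is.data.frame(singles)) {
    if (!all(c("agent", "value") %in% names(singles))) {
      stop("'singles' needs columns agent, value", call. = FALSE)
    }
    sv <- stats::setNames(as.numeric(singles$value), as.character(singles$agent))
  } else {
    sv <- singles
    if (is.null(names(sv))) stop("'singles' vector must be named", call. = FALSE)
  }
  dup <- unique(names(sv)[duplicated(names(sv))])
  if (length(dup)) {
    stop("duplicate single agent(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(combos) || nrow(as.data.frame(combos)) == 0L) {
    combos <- data.frame(agent_a = character(0), agent_b = character(0),
                         value = numeric(0), stringsAsFactors = FALSE)
  }
  combos <- as.data.frame(combos, stringsAsFactors = FALSE)
  if (!all(c("agent_a", "agent_b", "value") %in% names(combos))) {
    stop("'combos' needs columns agent_a, agent_b, value", call. = FALSE)
  }
  unknown <- setdiff(unique(c(combos$agent_a, combos$agent_b)), names(sv))
  if (length(unknown)) {
    stop("combination references unknown single agent(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", 2L * nrow(combos))
  ri <- 0L
  for (i in seq_len(nrow(combos))) {
    for (ref in c(combos$agent_a[i], combos$agent_b[i])) {
      imp <- improvement_pct(combos$value[i], sv[[ref]], mode = mode)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        agent_a = combos$agent_a[i], agent_b = combos$agent_b[i],
        combo_value = combos$value[i], reference = ref,
        single_value = unname(sv[[ref]]),
        improvement = imp,
        improvement_rounded = round_half_away(imp),
        stringsAsFactors = FALSE)
    }
  }
  improvements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(agent_a = character(0), agent_b = character(0),
               combo_value = numeric(0), reference = character(0),
               single_value = numeric(0), improvement = numeric(0),
               improvement_rounded = numeric(0), stringsAsFactors = FALSE)
  rownames(improvements) <- NULL
  structure(list(singles = sv, combos = combos,
                 improvements = improvements, mode = mode),
            class = "synergy_table")
}

#' @export
print.synergy_table <- function(x, ...) {
  cat(sprintf("synergy_table (%s mode): %d singles, %d combinations\n",
              x$mode, length(x$singles), nrow(x$combos)))
  if (nrow(x$improvements)) print(x$improvements) else
    cat("no combinations: improvements empty\n")
  invisible(x)
}

#' Read single-agent values from CSV
#'
#' Expects columns \code{agent,value}.
#' @param path CSV path.
#' @return data.frame with columns \code{agent}, \code{value}.
#' @export
read_singles <- function(path) {
  if (!file.exists(path)) stop("singles file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("agent", "value") %in% names(df))) {
    stop("singles CSV needs columns agent,value", call. = FALSE)
  }
  df
}

#' Read pairwise combination values from CSV
#'
#' Expects columns \code{agent_a,agent_b,value}.
#' @param path CSV path.
#' @return data.frame with columns \code{agent_a}, \code{agent_b},
#'   \code{value}.
#' @export
read_combos <- function(path) {
  if (!file.exists(path)) stop("combos file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("agent_a", "agent_b", "value") %in% names(df))) {
    stop("combos CSV needs columns agent_a,agent_b,value", call. = FALSE)
  }
  df
}

#' Write a synergy table's improvements to CSV
#'
#' @param x a \code{synergy_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_synergy_table <- function(x, path) {
  stopifnot(inherits(x, "synergy_table"))
  utils::write.csv(x$improvements, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
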