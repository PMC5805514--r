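# The published 13-case rule-vote fixture and its re-classification.

#' Load the published per-case rule votes
#'
#' Reads the shipped fixture encoding, for each of the 13 cases of the
#' reference cohort, the vote set printed for every rule (`-` =
#' inapplicable; the one ambiguous rule-5 cell, "n,e or s,p,n", is
#' treated as inapplicable with its text kept as the note), the printed
#' conclusion, and the rule restriction applied to the suspected
#' independent-origin case (rules 1 and 5 only).
#'
#' @param path fixture path; defaults to the copy shipped with the
#'   package.
#' @return Named list, one element per case, each with `rule_votes` (list
#'   of [rule_vote]), `conclusion` (character vector of modes),
#'   `conclusion_confidence`, and `restrict` (integer rule ids or NULL).
#' @export
table2_votes <- function(path = system.file("extdata", "table2_votes.tsv",
                                            package = "moeinfer")) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  parse_cell <- function(cell, rule_id) {
    cell <- trimws(cell)
    if (cell == "-" || cell == "")
      return(rule_vote(rule_id, applicable = FALSE, note = "not applied"))
    if (grepl(" or ", cell))
      return(rule_vote(rule_id, applicable = FALSE, note = cell))
    rule_vote(rule_id, toupper(strsplit(cell, ",")[[1]]))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    votes <- lapply(1:5, function(r)
      parse_cell(df[[paste0("rule", r)]][i], r))
    concl <- trimws(df$conclusion[i])
    low <- grepl("most likely", concl)
    concl <- sub("^most likely\\s+", "", concl)
    restrict <- trimws(df$restrict[i])
    list(case = df$case[i], rule_votes = votes,
         conclusion = toupper(strsplit(concl, ",")[[1]]),
         conclusion_confidence = if (low) "low" else "normal",
         restrict = if (is.na(restrict) || restrict == "") NULL
         else as.integer(strsplit(restrict, ",")[[1]]))
  })
  names(out) <- df$case
  out
}

#' Re-derive the published conclusions by majority vote
#'
#' Applies [majority_vote()] to the fixture's per-rule vote sets
#' (honoring each case's rule restriction) and compares the result with
#' the printed conclusion column.
#'
#' @param votes output of [table2_votes()].
#' @return `data.frame` with one row per case: `case`, `final` (derived
#'   call, comma-joined), `confidence`, `expected` (printed conclusion),
#'   `expected_confidence`, `matches`.
#' @export
#' @examples
#' all(classify_table2()$matches)
classify_table2 <- function(votes = table2_votes()) {
  rows <- lapply(votes, function(v) {
    call <- majority_vote(v$rule_votes, restrict_to_rules = v$restrict,
                          case_id = v$case)
    data.frame(
      case = v$case,
      final = paste(call$final, collapse = ","),
      confidence = call$confidence,
      expected = paste(v$conclusion, collapse = ","),
      expected_confidence = v$conclusion_confidence,
      matches = identical(sort(call$final), sort(v$conclusion)) &&
        call$confidence == v$conclusion_confidence,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level mode frequencies from the fixture
#'
#' Summarizes the derived calls: the percentage of cases concluding
#' stepwise, parallel, or their tie, and the counts of eruptive and
#' neutral cases.
#'
#' @param votes output of [table2_votes()].
#' @return List with `n_cases`, `pct_stepwise_parallel` (rounded to the
#'   nearest 5%), `n_eruptive`, `n_neutral`.
#' @export
moe_frequencies <- function(votes = table2_votes()) {
  calls <- lapply(votes, function(v)
    majority_vote(v$rule_votes, restrict_to_rules = v$restrict,
                  case_id = v$case)$final)
  is_sp <- vapply(calls, function(f)
    length(f) > 0 && !identical(f, "unclassifiable") &&
      all(f %in% c("S", "P")), logical(1))
  list(n_cases = length(calls),
       pct_stepwise_parallel = 5 * round(100 * mean(is_sp) / 5),
       n_eruptive = sum(vapply(calls, identical, logical(1), "E")),
       n_neutral = sum(vapply(calls, identical, logical(1), "N")))
}
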