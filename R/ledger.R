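#' Create a privacy ledger
#'
#' Sequential composition: the cumulative privacy loss of multiple DP releases
#' from the same data equals the sum of their epsilons. The ledger records
#' every expenditure against a fixed total budget and refuses any release that
#' would exceed it.
#'
#' @param budget total privacy budget, > 0.
#' @return a `privacy_ledger` with an empty entry table.
#' @export
privacy_ledger <- function(budget) {
  check_positive(budget, "budget")
  structure(
    list(budget = budget,
         entries = tibble::tibble(label = character(), epsilon = numeric()),
         total_spent = 0),
    class = "privacy_ledger"
  )
}

#' Record an epsilon expenditure against the budget
#'
#' Appends an entry and adds its epsilon to the running total. If the new
#' total would exceed the budget the ledger is returned unchanged inside a
#' budget error naming the remaining budget.
#'
#' @param ledger a [privacy_ledger()].
#' @param label short description of the released query.
#' @param epsilon privacy loss of the release, > 0.
#' @return the updated ledger.
#' @export
privacy_accountant <- function(ledger, label, epsilon) {
  stopifnot(inherits(ledger, "privacy_ledger"))
  check_positive(epsilon, "epsilon")
  new_total <- sum(ledger$entries$epsilon) + epsilon
  if (new_total > ledger$budget) {
    abort(paste0("privacy budget exceeded: spending ", signif(epsilon, 6),
                 " on '", label, "' needs more than the remaining ",
                 signif(ledger$budget - ledger$total_spent, 6), "."),
          class = "dpcc_budget_error")
  }
  ledger$entries <- dplyr::bind_rows(
    ledger$entries, tibble::tibble(label = label, epsilon = epsilon))
  ledger$total_spent <- sum(ledger$entries$epsilon)
  ledger
}

#' @rdname privacy_accountant
#' @export
spend_epsilon <- privacy_accountant

#' Remaining privacy budget
#' @param ledger a [privacy_ledger()].
#' @return non-negative scalar.
#' @export
remaining_budget <- function(ledger) {
  stopifnot(inherits(ledger, "privacy_ledger"))
  ledger$budget - ledger$total_spent
}

#' @export
print.privacy_ledger <- function(x, ...) {
  cat("Privacy ledger: spent", signif(x$total_spent, 6), "of", x$budget,
      "across", nrow(x$entries), "releases\n")
  if (nrow(x$entries)) print(x$entries, n = 10)
  invisible(x)
}

#' Serialize a privacy ledger to JSON (entries kept in order)
#' @param ledger a [privacy_ledger()].
#' @param path output path.
#' @return `path`, invisibly; `read_ledger()` returns the ledger.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "privacy_ledger"))
  jsonlite::write_json(
    list(budget = ledger$budget, total_spent = ledger$total_spent,
         entries = ledger$entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- privacy_ledger(raw$budget)
  if (length(raw$entries)) {
    entries <- tibble::as_tibble(raw$entries)
    for (i in seq_len(nrow(entries))) {
      out <- privacy_accountant(out, entries$label[i], entries$epsilon[i])
    }
  }
  out
}
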