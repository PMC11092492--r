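#' Enumerate the single-digit-result arithmetic problem space
#'
#' Lists every addition pair \eqn{(a, b)} with \eqn{a, b \in [0, 18]} and
#' \eqn{a + b \le 18}, and every subtraction pair with \eqn{a - b \ge 0}:
#' 380 unique problems, 190 per operator, each with a result in 0..18.
#' Rows follow the canonical ordering used throughout the package (and by
#' the representational-similarity matrices): additions before subtractions,
#' then ascending result, then ascending first operand.
#'
#' @return A tibble with columns `operand_a`, `operand_b`, `operator`
#'   (`"add"` or `"sub"`) and `result`, 380 rows.
#' @examples
#' probs <- enumerate_problems()
#' nrow(probs)                      # 380
#' table(probs$operator)            # 190 add, 190 sub
#' @export
enumerate_problems <- function() {
  add <- purrr::map_dfr(0:18, function(r) {
    a <- 0:r
    tibble(operand_a = a, operand_b = r - a, operator = "add", result = r)
  })
  sub <- purrr::map_dfr(0:18, function(r) {
    a <- r:18
    tibble(operand_a = a, operand_b = a - r, operator = "sub", result = r)
  })
  bind_rows(add, sub)
}

#' Format a problem row as text
#' @param problems data frame with `operand_a`, `operand_b`, `operator`.
#' @return character vector like `"3 + 4"`.
#' @export
format_problem <- function(problems) {
  sym <- ifelse(problems$operator == "add", "+", "-")
  paste(problems$operand_a, sym, problems$operand_b)
}

check_problems <- function(problems) {
  stopifnot(all(c("operand_a", "operand_b", "operator", "result") %in%
                  names(problems)))
  ok_add <- problems$operator == "add" &
    problems$result == problems$operand_a + problems$operand_b
  ok_sub <- problems$operator == "sub" &
    problems$result == problems$operand_a - problems$operand_b
  if (!all(ok_add | ok_sub) ||
      any(problems$result < 0 | problems$result > 18) ||
      any(problems$operand_a < 0 | problems$operand_a > 18) ||
      any(problems$operand_b < 0 | problems$operand_b > 18)) {
    abort("invalid arithmetic problem table")
  }
  invisible(problems)
}
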