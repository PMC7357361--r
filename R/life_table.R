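# Synthetic background-mortality life table. The study's national
# age-specific non-cardiac mortality schedule is not published, so a
# two-parameter Gompertz hazard stands in: smooth, monotone in age, and
# calibratable to a first-year probability and a hazard doubling time.

#' Gompertz background-mortality life table
#'
#' Annual probabilities of death from non-cardiac causes,
#' `q(age) = 1 - exp(-a exp(b (age - start_age)))`, for
#' `start_age, ..., start_age + n_years - 1`.
#'
#' @param a Base annual hazard at `start_age` (> 0).
#' @param b Log-hazard slope per year of age (>= 0).
#' @param start_age First age in the table.
#' @param n_years Number of annual entries (>= 1).
#' @return A data frame of class `life_table` with columns `age` and `q`.
#'   Probabilities that would exceed 1 are clamped with a warning.
#' @examples
#' gompertz_life_table(0.01, 0.09, 60, 10)
#' @export
gompertz_life_table <- function(a, b, start_age, n_years) {
  stopifnot(is.numeric(a), is.numeric(b), n_years >= 1)
  if (a <= 0) stop("gompertz_life_table: base hazard a must be > 0")
  if (b < 0) stop("gompertz_life_table: slope b must be >= 0")
  age <- start_age + seq_len(n_years) - 1L
  q <- 1 - exp(-a * exp(b * (age - start_age)))
  if (any(q > 1)) {
    warning("gompertz_life_table: probabilities > 1 clamped to 1")
    q <- pmin(q, 1)
  }
  structure(data.frame(age = as.integer(age), q = q),
            class = c("life_table", "data.frame"))
}

#' Calibrate a Gompertz life table to a target first-year probability
#'
#' Chooses `a` so that `q(start_age)` equals `q_target_at_start` exactly and
#' `b = log(2) / doubling_time`, so the hazard doubles every `doubling_time`
#' years.
#'
#' @param q_target_at_start First-year non-cardiac death probability, in
#'   (0, 1).
#' @param doubling_time Hazard doubling time in years (finite, > 0).
#' @param start_age,n_years As in [gompertz_life_table()].
#' @return A `life_table` data frame.
#' @examples
#' lt <- calibrate_life_table(0.01, 8, 60, 10)
#' lt$q[1]            # exactly 0.01
#' lt$q[9] / lt$q[1]  # ~2 (hazard doubles every 8 years)
#' @export
calibrate_life_table <- function(q_target_at_start, doubling_time,
                                 start_age, n_years) {
  if (!is.numeric(q_target_at_start) || q_target_at_start <= 0 ||
      q_target_at_start >= 1)
    stop("calibrate_life_table: q_target_at_start must be in (0, 1)")
  if (!is.numeric(doubling_time) || !is.finite(doubling_time) ||
      doubling_time <= 0)
    stop("calibrate_life_table: doubling_time must be finite and > 0")
  a <- -log(1 - q_target_at_start)
  b <- log(2) / doubling_time
  gompertz_life_table(a, b, start_age, n_years)
}

#' Look up the annual non-cardiac death probability at an age
#'
#' @param lt A `life_table`.
#' @param age Age in whole years; must be present in the table.
#' @return The annual probability `q` at that age.
#' @export
life_table_q <- function(lt, age) {
  i <- match(age, lt$age)
  if (any(is.na(i))) stop("life_table_q: age ", paste(age[is.na(i)], collapse = ", "),
                          " not covered by the life table")
  lt$q[i]
}

#' Read / write a life table as two-column CSV
#'
#' Plain CSV with header `age,q`.
#'
#' @param path File path.
#' @return `read_life_table` returns a `life_table`; `write_life_table`
#'   returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "q") %in% names(d)))
    stop("life table CSV must have columns 'age' and 'q'")
  if (any(d$q < 0 | d$q > 1)) stop("life table q outside [0, 1]")
  structure(data.frame(age = as.integer(d$age), q = as.numeric(d$q)),
            class = c("life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param lt A `life_table` to write.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(lt[, c("age", "q")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
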