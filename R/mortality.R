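MORTALITY_PRESETS <- list(
  default = matrix(c(1.00, 0.80, 0.50,
                     0.90, 0.70, 0.40), nrow = 2, byrow = TRUE),
  minimum = matrix(c(0.60, 0.60, 0.40,
                     0.50, 0.50, 0.40), nrow = 2, byrow = TRUE),
  maximum = matrix(c(1.00, 1.00, 0.50,
                     0.90, 0.90, 0.50), nrow = 2, byrow = TRUE)
)

#' Host mortality rates by vulnerability class
#'
#' Mortality fractions for trees expressing pine wilt disease, by age
#' class (at most 20 yr / older than 20 yr) and species susceptibility
#' (susceptible / intermediate / resistant). Three literature-based
#' presets ship with the package:
#'
#' * `default` (most likely): young 100/80/50%, old 90/70/40%
#' * `minimum`: young 60/60/40%, old 50/50/40%
#' * `maximum`: young 100/100/50%, old 90/90/50%
#'
#' @param preset One of `"default"`, `"minimum"`, `"maximum"`, or a 2 x 3
#'   numeric matrix of mortality fractions (rows: young, old; columns:
#'   susceptible, intermediate, resistant).
#' @return A 2 x 3 matrix of class `mortality_table` with dimnames
#'   `age_class` x `susceptibility` and a `"preset"` attribute.
#' @examples
#' mortality_table("maximum")
#' @export
mortality_table <- function(preset = c("default", "minimum", "maximum")) {
  if (is.matrix(preset)) {
    m <- preset
    name <- "custom"
  } else {
    name <- match.arg(preset)
    m <- MORTALITY_PRESETS[[name]]
  }
  if (!is.numeric(m) || !all(dim(m) == c(2L, 3L)))
    stop("mortality table must be a 2 x 3 numeric matrix", call. = FALSE)
  if (any(m < 0) || any(m > 1))
    stop("mortality fractions must lie in [0, 1]", call. = FALSE)
  dimnames(m) <- list(age_class = c("young", "old"),
                      susceptibility = c("susceptible", "intermediate",
                                         "resistant"))
  structure(m, class = c("mortality_table", "matrix"), preset = name)
}

#' @export
print.mortality_table <- function(x, ...) {
  cat(sprintf("<mortality_table> preset '%s' (fraction of trees killed)\n",
              attr(x, "preset")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

# mortality fraction per row of a stock table
mortality_for_stock <- function(stock, mortality) {
  stopifnot(inherits(mortality, "mortality_table"))
  mortality[cbind(match(stock$age_class, rownames(mortality)),
                  match(stock$susceptibility, colnames(mortality)))]
}
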