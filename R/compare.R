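#' Scanner record of regional parameter values
#'
#' One scanner's regional quantification results (BP_ND or late-window
#' ratios) for one or more subjects and tracers.
#'
#' @param scanner Scanner label.
#' @param region Character vector of region names.
#' @param value Numeric parameter values, same length as `region`.
#' @param subject Subject id(s) (recycled).
#' @param tracer Tracer label(s) (recycled).
#' @return A data frame of class `scanner_record` with columns `scanner`,
#'   `subject`, `tracer`, `region`, `value`.
#' @export
scanner_record <- function(scanner, region, value, subject = "subject1",
                           tracer = "tracer") {
  stopifnot(length(region) == length(value))
  out <- data.frame(scanner = scanner, subject = subject, tracer = tracer,
                    region = region, value = as.numeric(value))
  class(out) <- c("scanner_record", "data.frame")
  out
}

#' Cross-scanner comparison report
#'
#' Element-wise ratios of regional parameter values between two scanners,
#' matched on subject, tracer and region. Percent deviation is defined as
#' `|ratio - 1| * 100`. Per-tracer mean ratios across subjects are the
#' arithmetic means of the per-subject ratios (mean of ratios, not ratio of
#' means).
#'
#' @param a,b [scanner_record()] data frames (numerator and denominator).
#' @return An object of class `comparison_report`: `regions` (per matched
#'   row: `subject`, `tracer`, `region`, `value_a`, `value_b`, `ratio`,
#'   `deviation_pct`) and `tracer_means` (`tracer`, `region`, `mean_ratio`,
#'   `n_subjects`), plus labels `scanner_a`, `scanner_b` and the deviation
#'   definition.
#' @export
scanner_ratio <- function(a, b) {
  for (df in list(a, b))
    if (!all(c("subject", "tracer", "region", "value") %in% names(df)))
      stop("records need columns subject, tracer, region, value")
  key_a <- paste(a$subject, a$tracer, a$region, sep = "\r")
  key_b <- paste(b$subject, b$tracer, b$region, sep = "\r")
  miss_in_b <- setdiff(key_a, key_b)
  miss_in_a <- setdiff(key_b, key_a)
  if (length(miss_in_b) || length(miss_in_a)) {
    fmt <- function(k) paste(gsub("\r", "/", k), collapse = ", ")
    stop("mismatched regions between records:",
         if (length(miss_in_b)) paste0(" missing in second record: ",
                                       fmt(miss_in_b)),
         if (length(miss_in_a)) paste0(" missing in first record: ",
                                       fmt(miss_in_a)))
  }
  m <- match(key_a, key_b)
  regions <- data.frame(subject = a$subject, tracer = a$tracer,
                        region = a$region, value_a = a$value,
                        value_b = b$value[m],
                        ratio = a$value / b$value[m])
  regions$deviation_pct <- abs(regions$ratio - 1) * 100
  agg <- stats::aggregate(ratio ~ tracer + region, data = regions, FUN = mean)
  names(agg)[names(agg) == "ratio"] <- "mean_ratio"
  n <- stats::aggregate(ratio ~ tracer + region, data = regions, FUN = length)
  agg$n_subjects <- n$ratio
  structure(list(regions = regions, tracer_means = agg,
                 scanner_a = a$scanner[1L], scanner_b = b$scanner[1L],
                 deviation_definition = "|ratio - 1| x 100"),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %s / %s, %d matched regions\n",
              x$scanner_a, x$scanner_b, nrow(x$regions)))
  print(utils::head(x$regions, 10L))
  invisible(x)
}
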