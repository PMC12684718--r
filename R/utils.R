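# Internal helpers: classed conditions, seeded evaluation, TSV dialect.

pd_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "phylodepth_error"), call = call))
}

pd_warn <- function(msg, class = "phylodepth_warning") {
  warning(warningCondition(msg, class = class))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded stages never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation from one root seed. Kept below 2^31.
deriveSeed <- function(seed, a, b = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 7919 +
    as.numeric(a) * 104729 + as.numeric(b) * 131
  as.integer(s %% 2147483563) + 1L
}

# TSV dialect: tab-separated, UTF-8, '.' decimal, header mandatory, missing
# values written as empty fields (never "NA").
writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- formatNum(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# 15 significant digits: lossless roundtrip for doubles at the precision the
# I/O contract asks for (12 significant digits), deterministic formatting.
formatNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.15g", v)
  }, character(1))
  out
}

readTsv <- function(path) {
  if (!file.exists(path)) {
    pd_stop(sprintf("file not found: %s", path), "phylodepth_io_error")
  }
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    pd_stop(sprintf("%s: missing required column(s): %s", what,
                    paste(missing, collapse = ", ")),
            "phylodepth_schema_error")
  }
  invisible(TRUE)
}

checkNumericColumn <- function(x, col, what) {
  if (is.numeric(x)) return(x)
  conv <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(conv) & !is.na(x))
  if (length(bad) > 0) {
    pd_stop(sprintf("%s: non-numeric value in column '%s' at row %d",
                    what, col, bad[1]), "phylodepth_parse_error")
  }
  conv
}

# Percent-scaled fraction columns (any value > 1) are converted to fractions.
# Values already in [0, 1] are never rescaled (involution-safe).
fractionize <- function(x, col, what) {
  over <- !is.na(x) & x > 1
  if (any(over)) {
    pd_warn(sprintf("%s: column '%s' appears percent-scaled; dividing %d value(s) by 100",
                    what, col, sum(over)), "phylodepth_percent_rescale")
    x[over] <- x[over] / 100
  }
  x
}
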