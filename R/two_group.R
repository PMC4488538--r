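#' Two-group diagnostic sample
#'
#' Container for the measurements of a diagnostic marker in the non-diseased
#' group (`x`, size `m`) and the diseased group (`y`, size `n`).  The diseased
#' group is assumed stochastically larger; no automatic re-orientation is
#' performed (see [youden_empirical()]).
#'
#' @param x Numeric vector of marker values for the non-diseased group
#'   (length `m >= 1`, all finite).  Ties within and across groups are allowed.
#' @param y Numeric vector of marker values for the diseased group
#'   (length `n >= 1`, all finite).
#'
#' @return An object of class `"two_group_sample"`: a list with components
#'   `x` and `y`.
#' @examples
#' s <- two_group_sample(rnorm(30), rnorm(20, mean = 1))
#' s
#' @export
two_group_sample <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must contain at least one observation", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all measurements must be finite", call. = FALSE)
  structure(list(x = x, y = y), class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat(sprintf("Two-group diagnostic sample: m = %d (non-diseased), n = %d (diseased)\n",
              length(x$x), length(x$y)))
  cat(sprintf("  non-diseased range: [%g, %g]\n", min(x$x), max(x$x)))
  cat(sprintf("  diseased range:     [%g, %g]\n", min(x$y), max(x$y)))
  invisible(x)
}

## Coerce loose (x, y) arguments to a validated sample.  Exported functions
## accept either a two_group_sample or two raw vectors.
as_two_group <- function(x, y = NULL) {
  if (inherits(x, "two_group_sample")) return(x)
  if (is.null(y))
    stop("supply a 'two_group_sample' or both 'x' and 'y' vectors", call. = FALSE)
  two_group_sample(x, y)
}

#' Read a two-group sample from delimited text files
#'
#' Reads marker values in one of three layouts: a single long file with a
#' value column and a group-label column (`layout = "long"`), a single file
#' with one named column per group (`layout = "wide"`), or two separate
#' one-column files (`layout = "two_file"`).  Lines starting with `#` and
#' blank lines are ignored.
#'
#' When `group_labels` is not given for the long layout, exactly two distinct
#' labels must be present and the first label encountered in file order is
#' taken as the non-diseased group.
#'
#' @param file Path to the input file (long and wide layouts), or a character
#'   vector of two paths `c(non_diseased, diseased)` for `layout = "two_file"`.
#' @param layout One of `"long"`, `"wide"`, `"two_file"`.
#' @param group_labels Character vector of length 2,
#'   `c(non_diseased_label, diseased_label)`.  For the long layout these are
#'   matched against the label column; for the wide layout against column
#'   names.  Optional when the file determines them unambiguously.
#' @param sep Field separator (default `","`; use `"\t"` for TSV).
#' @param value_col,label_col Column names (or indices) for the long layout;
#'   defaults: first column values, second column labels.
#' @return A [two_group_sample()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("value,group", "1.2,ctrl", "2.3,case", "0.8,ctrl"), f)
#' read_two_group(f, group_labels = c("ctrl", "case"))
#' @export
read_two_group <- function(file, layout = c("long", "wide", "two_file"),
                           group_labels = NULL, sep = ",",
                           value_col = 1L, label_col = 2L) {
  layout <- match.arg(layout)
  if (layout == "two_file") {
    if (length(file) != 2L)
      stop("layout 'two_file' needs two paths: c(non_diseased, diseased)", call. = FALSE)
    vals <- lapply(file, function(f) {
      v <- utils::read.table(f, sep = sep, comment.char = "#",
                             blank.lines.skip = TRUE, header = FALSE)[[1L]]
      if (!is.numeric(v)) stop("non-numeric values in ", f, call. = FALSE)
      if (length(v) == 0L) stop("empty group in ", f, call. = FALSE)
      v
    })
    return(two_group_sample(vals[[1L]], vals[[2L]]))
  }
  tab <- utils::read.table(file, sep = sep, comment.char = "#", header = TRUE,
                           blank.lines.skip = TRUE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (is.null(group_labels)) {
      if (ncol(tab) != 2L)
        stop("wide layout without 'group_labels' needs exactly two columns; found: ",
             paste(names(tab), collapse = ", "), call. = FALSE)
      group_labels <- names(tab)
    }
    miss <- setdiff(group_labels, names(tab))
    if (length(miss))
      stop("columns not found: ", paste(miss, collapse = ", "), call. = FALSE)
    x <- tab[[group_labels[1L]]]; y <- tab[[group_labels[2L]]]
    return(two_group_sample(x[!is.na(x)], y[!is.na(y)]))
  }
  ## long layout
  vals <- tab[[value_col]]
  labs <- as.character(tab[[label_col]])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(vals)))))
    stop("non-numeric measurement value at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  found <- unique(labs)
  if (is.null(group_labels)) {
    if (length(found) != 2L)
      stop("expected exactly 2 group labels, found ", length(found), ": ",
           paste(found, collapse = ", "), call. = FALSE)
    group_labels <- found            # first-seen label = non-diseased
  }
  extra <- setdiff(found, group_labels)
  if (length(extra))
    stop("unexpected group label(s): ", paste(extra, collapse = ", "), call. = FALSE)
  x <- vals[labs == group_labels[1L]]
  y <- vals[labs == group_labels[2L]]
  if (length(x) == 0L || length(y) == 0L)
    stop("empty group: no rows labelled '",
         group_labels[[which(c(length(x), length(y)) == 0L)[1L]]], "'", call. = FALSE)
  two_group_sample(x, y)
}

#' Write a two-group sample as a long-format CSV fixture
#'
#' Writes a `value,group` CSV with `#`-prefixed header comments recording the
#' provenance metadata supplied in `meta` (e.g. distribution family,
#' parameters, true index, RNG seed).  The file round-trips through
#' [read_two_group()].
#'
#' @param sample A [two_group_sample()].
#' @param file Output path.
#' @param group_labels Labels written for the two groups.
#' @param meta Named list of scalar metadata written as `# name: value` lines.
#' @return `file`, invisibly.
#' @export
write_two_group <- function(sample, file,
                            group_labels = c("non_diseased", "diseased"),
                            meta = list()) {
  sample <- as_two_group(sample)
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 15)), con)
  writeLines("value,group", con)
  writeLines(c(sprintf("%.17g,%s", sample$x, group_labels[1L]),
               sprintf("%.17g,%s", sample$y, group_labels[2L])), con)
  invisible(file)
}

#' Acid-phosphatase levels in a prostate-cancer nodal-involvement study
#'
#' Serum acid-phosphatase measurements for 53 prostate-cancer patients, 33
#' without nodal involvement (non-diseased group) and 20 with nodal
#' involvement (diseased group).  A classical data set used to illustrate
#' optimal cut-point selection: the marker is used to predict nodal
#' involvement without surgery.
#'
#' @return A [two_group_sample()] with `m = 33` and `n = 20`.
#' @examples
#' s <- prostate_nodal()
#' youden_empirical(s)
#' @export
prostate_nodal <- function() {
  f <- system.file("extdata", "prostate_acid_phosphatase.csv",
                   package = "youdenci", mustWork = TRUE)
  read_two_group(f, layout = "long", group_labels = c("nodal_neg", "nodal_pos"))
}
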