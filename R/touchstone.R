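# Touchstone v1 (.s10p) single-frequency import/export. For n > 2 ports the
# network data is row-major: each matrix row starts on a new line with at
# most four complex pairs per line; the frequency prefixes the first line.

#' Write an S-matrix to a Touchstone .s10p file
#'
#' Real/imaginary (RI) format, frequency in Hz, 50-ohm reference.
#'
#' @param s An [smatrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(s, path) {
  stopifnot(inherits(s, "smatrix"))
  lines <- c("! 10-port single-frequency S-parameters",
             "# HZ S RI R 50")
  fmt <- function(x) sprintf("%.12e %.12e", Re(x), Im(x))
  for (row in 1:10) {
    vals <- s$entries[row, ]
    chunks <- split(vals, ceiling(seq_along(vals) / 4))
    for (j in seq_along(chunks)) {
      body <- paste(vapply(chunks[[j]], fmt, character(1)), collapse = " ")
      prefix <- if (row == 1L && j == 1L) sprintf("%.10e ", s$frequency)
                else "  "
      lines <- c(lines, paste0(prefix, body))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an S-matrix from a Touchstone .s10p file
#'
#' Supports the subset written by [write_touchstone()]: one frequency
#' point, RI format. HZ/KHZ/MHZ/GHZ frequency units are honored.
#'
#' @param path File path.
#' @param tol Reciprocity tolerance passed to [smatrix()].
#' @return An [smatrix].
#' @export
read_touchstone <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  opt <- lines[startsWith(lines, "#")]
  if (length(opt) != 1L) stop("expected exactly one Touchstone option line")
  toks <- toupper(strsplit(sub("^#", "", opt), "\\s+")[[1]])
  toks <- toks[nzchar(toks)]
  unit <- if (length(toks) >= 1) toks[1] else "GHZ"
  mult <- switch(unit, HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9,
                 stop("unsupported frequency unit: ", unit))
  if (!"S" %in% toks) stop("only S-parameter Touchstone files are supported")
  if (!"RI" %in% toks) stop("only RI-format Touchstone files are supported")
  nums <- as.numeric(unlist(strsplit(
    paste(lines[!startsWith(lines, "#")], collapse = " "), "\\s+")))
  nums <- nums[!is.na(nums)]
  if (length(nums) != 1 + 200)
    stop("expected one frequency point with 100 complex entries, got ",
         length(nums), " numbers")
  freq <- nums[1] * mult
  re <- nums[seq(2, 201, by = 2)]
  im <- nums[seq(3, 201, by = 2)]
  entries <- matrix(complex(real = re, imaginary = im), 10, 10, byrow = TRUE)
  smatrix(entries, frequency = freq, tol = tol)
}
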