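# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @keywords internal
slugify <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", "-", x)
  x <- gsub("^-+|-+$", "", x)
  x[x == ""] <- "x"
  x
}

# Shortest decimal rendering that round-trips the double exactly (capped at
# 17 significant digits); keeps serialized ontologies byte-stable while
# printing 0.93 as "0.93", not "0.93000000000000005".
format_shortest <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", flag = "#")
      s <- sub("\\.$", "", s)
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g")
  }, character(1))
}

# locale-independent ordering used everywhere determinism matters
canonical_order <- function(x) order(x, method = "radix")

canonical_sort <- function(x) {
  if (length(x) == 0L) return(character(0))
  x[canonical_order(x)]
}

# split a delimited multi-value cell; empty string -> character(0)
split_multi <- function(x, delim = "|") {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  parts <- trimws(strsplit(x, delim, fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

join_multi <- function(x, delim = "|") paste(x, collapse = delim)

stop_ccn <- function(code, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), code = code,
                      class = c(paste0("ccn2ont_", code), "ccn2ont_error")))
}

is_curie <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.]*:\\S+$", x)

curie_prefix <- function(x) sub(":.*$", "", x)

new_report <- function() {
  data.frame(code = character(0), severity = character(0),
             entity = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

add_finding <- function(report, code, entity, message,
                        severity = "ERROR") {
  rbind(report, data.frame(code = code, severity = severity,
                           entity = entity, message = message,
                           stringsAsFactors = FALSE))
}

# write lines with fixed "\n" endings and UTF-8 encoding (byte determinism)
write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
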