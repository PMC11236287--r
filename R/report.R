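#' @importFrom jsonlite base64_enc write_json
NULL

.htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# table -> HTML, escaping every cell
.htmlTable <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("<p><em>empty table</em></p>")
  fmt <- function(v) if (is.numeric(v)) signif(v, 6) else v
  df[] <- lapply(df, fmt)
  head <- paste0("<tr>", paste0("<th>", .htmlEscape(colnames(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", .htmlEscape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table>", head, paste(body, collapse = "\n"), "</table>")
}

# PNG file -> <img> with a base64 data URI (self-contained, no fetches)
.htmlImage <- function(path, alt) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  sprintf('<img alt="%s" src="data:image/png;base64,%s"/>',
          .htmlEscape(alt), jsonlite::base64_enc(bytes))
}

#' Render the consolidated HTML report
#'
#' Produces a single self-contained HTML file: all figures are embedded as
#' base64 data URIs and all tables inlined, so the report opens with zero
#' external asset requests. A parameters section records g, its null
#' p-value, the physical-distance definition (intergenic gap, clamped at 0),
#' the D_C pooling rule and the run metadata.
#'
#' @param path output HTML path.
#' @param title report title.
#' @param params named list echoed into the parameters section.
#' @param tables named list of data.frames.
#' @param figures named character vector of PNG paths. A missing file is
#'   reported as an inline warning block and flagged in the return value.
#' @return A list with `path` and `ok` (FALSE when any figure was missing).
#' @export
renderHTMLReport <- function(path, title, params = list(), tables = list(),
                             figures = character(0)) {
  css <- paste(
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:0.85em}",
    "img{max-width:100%;border:1px solid #ddd;margin:0.5em 0}",
    ".warn{background:#FFF3CD;border:1px solid #B8860B;padding:0.8em}",
    "h2{border-bottom:1px solid #ccc}")
  parts <- c(sprintf("<!DOCTYPE html><html><head><meta charset='utf-8'/>"),
             sprintf("<title>%s</title><style>%s</style></head><body>",
                     .htmlEscape(title), css),
             sprintf("<h1>%s</h1>", .htmlEscape(title)))
  ok <- TRUE
  if (length(params) > 0L) {
    pdf_ <- data.frame(parameter = names(params),
                       value = vapply(params, function(v)
                         paste(format(v), collapse = " "), ""),
                       stringsAsFactors = FALSE)
    parts <- c(parts, "<h2>Parameters and analysis decisions</h2>",
               .htmlTable(pdf_))
  }
  for (nm in names(figures)) {
    parts <- c(parts, sprintf("<h2>%s</h2>", .htmlEscape(nm)))
    if (file.exists(figures[[nm]])) {
      parts <- c(parts, .htmlImage(figures[[nm]], nm))
    } else {
      ok <- FALSE
      parts <- c(parts, sprintf(
        "<div class='warn'>figure missing on disk: %s</div>",
        .htmlEscape(figures[[nm]])))
    }
  }
  for (nm in names(tables))
    parts <- c(parts, sprintf("<h2>%s</h2>", .htmlEscape(nm)),
               .htmlTable(tables[[nm]]))
  parts <- c(parts, "</body></html>")
  writeLines(parts, path)
  list(path = path, ok = ok)
}
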