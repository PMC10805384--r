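# Plain-text model configuration files: tab-separated sections
# [settings], [population], [projection], [external].

#' Write a model configuration to a text file
#'
#' @param config an \code{nc_config}.
#' @param path output file.
#' @export
write_model_config <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[settings]", con)
  writeLines(sprintf("dt\t%.10g", config$dt), con)
  writeLines(sprintf("record_rate\t%.10g", config$record_rate), con)
  writeLines(sprintf("duration\t%.10g", config$duration), con)
  writeLines(sprintf("H\t%.10g", config$H), con)
  writeLines("", con)
  wtab <- function(name, df) {
    writeLines(paste0("[", name, "]"), con)
    utils::write.table(format(df, digits = 12, trim = TRUE, scientific = NA),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("", con)
  }
  wtab("population", config$populations)
  wtab("projection", config$projections)
  wtab("external", config$external)
  invisible(path)
}

#' Read a model configuration from a text file
#'
#' @param path file written by [write_model_config()].
#' @return an \code{nc_config}.
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  sec_at <- grep("^\\[", lines)
  secs <- gsub("\\[|\\]", "", lines[sec_at])
  blocks <- Map(function(s, e) lines[s:e],
                sec_at + 1, c(sec_at[-1] - 1, length(lines)))
  names(blocks) <- secs
  get_tab <- function(name) {
    b <- blocks[[name]]
    b <- b[nzchar(b)]
    utils::read.table(text = b, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  st <- blocks[["settings"]]
  st <- st[nzchar(st)]
  kv <- do.call(rbind, strsplit(st, "\t"))
  settings <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  model_config(populations = get_tab("population"),
               projections = get_tab("projection"),
               external = get_tab("external"),
               dt = settings[["dt"]],
               record_rate = settings[["record_rate"]],
               duration = settings[["duration"]],
               H = settings[["H"]])
}

#' Load one of the shipped state configurations
#'
#' @param state \code{"waking"}, \code{"anesthesia"}, or \code{"seizure"}.
#' @return an \code{nc_config}.
#' @export
load_state_config <- function(state = c("waking", "anesthesia", "seizure")) {
  state <- match.arg(state)
  path <- system.file("extdata", paste0(state, ".cfg"), package = "neurocrit")
  if (!nzchar(path)) stop("no shipped configuration for state ", state)
  read_model_config(path)
}
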