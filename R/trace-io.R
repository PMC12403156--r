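# Canonical trace-table I/O: delimited text with a '#' key-value header
# block (dt, red_laser_start, and optional bg/noise_sd) followed by a
# four-column table: molecule_id, frame, i_donor, i_acceptor. Frame indices
# are 0-based.

#' Write traces to a trace table
#'
#' @param x An `"sm_cohort"`, a list of `"sm_trace"`, or a single trace.
#' @param file Output path (tab-separated text).
#' @param extra_header Named character vector of extra `# key=value` lines
#'   (e.g. provenance added by the pipeline).
#' @return `file`, invisibly.
#' @seealso [read_traces()], [write_truth()]
#' @export
write_traces <- function(x, file, extra_header = NULL) {
  traces <- as_trace_list(x)
  t1 <- traces[[1]]
  hdr <- c(dt = format(t1$dt, digits = 15),
           red_laser_start = as.character(t1$red_laser_start),
           bg = format(t1$bg %||% 0, digits = 15),
           noise_sd = format(t1$noise_sd %||% NA_real_, digits = 15))
  hdr <- c(hdr, extra_header)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(hdr), unname(hdr)), con)
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = tr$molecule_id,
               frame = seq_along(tr$i_d) - 1L,
               i_donor = round(tr$i_d, 3), i_acceptor = round(tr$i_a, 3),
               stringsAsFactors = FALSE)
  }))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a trace table
#'
#' @param file Path written by [write_traces()] (or any table in the same
#'   layout).
#' @return A list of `"sm_trace"` objects; header metadata is attached to
#'   each trace.
#' @export
read_traces <- function(file) {
  lines <- readLines(file)
  hl <- grep("^#", lines)
  meta <- list()
  for (l in lines[hl]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  tab <- read.delim(text = lines[-hl], stringsAsFactors = FALSE)
  stopifnot(all(c("molecule_id", "frame", "i_donor", "i_acceptor") %in%
                  colnames(tab)))
  dt <- as.numeric(meta$dt %||% "0.1")
  rls <- as.integer(meta$red_laser_start %||% NA)
  bg <- as.numeric(meta$bg %||% "0")
  nsd <- as.numeric(meta$noise_sd %||% NA)
  ids <- unique(tab$molecule_id)
  lapply(ids, function(id) {
    sub <- tab[tab$molecule_id == id, ]
    sub <- sub[order(sub$frame), ]
    structure(list(molecule_id = id, dt = dt,
                   i_d = sub$i_donor, i_a = sub$i_acceptor,
                   red_laser_start = if (is.na(rls)) nrow(sub) else rls,
                   bg = bg, noise_sd = nsd, i_total = NA_real_,
                   truth = NULL),
              class = "sm_trace")
  })
}

#' Write a cohort ground-truth table
#'
#' @param cohort An `"sm_cohort"`.
#' @param file Output path (tab-separated).
#' @export
write_truth <- function(cohort, file) {
  stopifnot(inherits(cohort, "sm_cohort"))
  write.table(cohort$truth, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

as_trace_list <- function(x) {
  if (inherits(x, "sm_cohort")) x$traces
  else if (inherits(x, "sm_trace")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "sm_trace"))) x
  else stop("expected an sm_cohort, an sm_trace, or a list of sm_trace")
}
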