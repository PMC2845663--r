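#' Export a genotype table in GENEPOP format
#'
#' Writes one POP block per stand with 4-digit diploid codes: allele_a is
#' coded 01, allele_b 02, so dosage 0 becomes 0101, 1 becomes 0102, 2
#' becomes 0202 and a missing call 0000. Marker names are listed one per
#' line after the title, the convention accepted by GENEPOP v4.
#'
#' @param table a \code{\link{genotype_table}}.
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @return \code{path}, invisibly.
#' @export
export_genepop <- function(table, path, title = "standscape export") {
  codes <- c("0101", "0102", "0202")
  lines <- c(title, table$map$marker_id)
  for (st in unique(table$samples$stand_id)) {
    lines <- c(lines, "Pop")
    idx <- which(table$samples$stand_id == st)
    for (i in idx) {
      g <- table$calls[i, ]
      gg <- ifelse(is.na(g), "0000", codes[g + 1L])
      lines <- c(lines, paste0(
        table$samples$stand_id[i], ":", table$samples$sample_id[i], " ,  ",
        paste(gg, collapse = " ")
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENEPOP file written by \code{\link{export_genepop}}
#'
#' Parses the two-allele 4-digit coding back into dosages. Sample ids and
#' stand assignment are recovered from the \code{stand:sample} id labels
#' written by the exporter. Year and transect order are not represented in
#' GENEPOP and come back as NA/0.
#'
#' @param path file path.
#' @param map a \code{\link{marker_map}}; marker names in the file must
#'   match it.
#' @return A \code{\link{genotype_table}}.
#' @export
read_genepop <- function(path, map) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("not a GENEPOP file: too short")
  pop_at <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_at)) stop("not a GENEPOP file: no Pop line")
  header <- lines[2:(pop_at[1] - 1L)]
  markers <- unlist(strsplit(header, "\\s*,\\s*"))
  markers <- markers[nzchar(markers)]
  if (!identical(markers, map$marker_id)) {
    stop("marker names in GENEPOP file do not match the marker map")
  }
  sample_id <- character(0); stand_id <- character(0)
  rows <- list()
  pop_idx <- 0L
  for (k in seq(pop_at[1], length(lines))) {
    ln <- lines[k]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) { pop_idx <- pop_idx + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("malformed GENEPOP record: ", ln)
    id <- trimws(parts[1])
    st <- sub(":.*$", "", id)
    sid <- sub("^[^:]*:", "", id)
    al <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(al) != nrow(map)) stop("wrong number of genotypes for ", id)
    a1 <- as.integer(substr(al, 1, 2)); a2 <- as.integer(substr(al, 3, 4))
    d <- (a1 - 1L) + (a2 - 1L)
    d[a1 == 0L | a2 == 0L] <- NA_integer_
    if (any(stats::na.omit(c(a1, a2)) > 2L)) stop(">2 alleles are not supported")
    rows[[length(rows) + 1L]] <- d
    sample_id <- c(sample_id, sid); stand_id <- c(stand_id, st)
  }
  calls <- do.call(rbind, rows)
  colnames(calls) <- map$marker_id
  genotype_table(
    calls,
    data.frame(
      sample_id = sample_id, stand_id = stand_id, year = NA_integer_,
      stringsAsFactors = FALSE
    ),
    map
  )
}
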