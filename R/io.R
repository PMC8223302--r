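#' Write a trait table to CSV
#'
#' Long-format CSV with columns accession, replicate, trait column id,
#' modality, trait, time, view, value.
#'
#' @param table a `trait_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table_csv <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  dat <- table$data
  long <- do.call(rbind, lapply(seq_len(nrow(table$info)), function(i) {
    col <- table$info$column[i]
    data.frame(accession = dat$accession, replicate = dat$replicate,
               column = col, modality = table$info$modality[i],
               trait = table$info$trait[i], time = table$info$time[i],
               view = table$info$view[i], value = dat[[col]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a trait table written by [write_trait_table_csv()]
#' @param path CSV path.
#' @return a `trait_table`.
#' @export
read_trait_table_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  recs <- long[long$view != "R", c("accession", "replicate", "view", "time",
                                   "modality", "trait", "value")]
  names(recs)[names(recs) == "view"] <- "treatment"
  assemble_trait_table(recs)
}
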