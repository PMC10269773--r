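#' Obtain the E. coli BL21(DE3) reference chromosome
#'
#' The reference-sequence checks (Chi census, genome GC) need the real
#' chromosome sequence (RefSeq NC_012971.2, ~4.6 Mb), which is too large to
#' ship with the package. This helper looks for a cached copy under
#' `tools::R_user_dir("smdnaseq", "cache")` (or a path given via
#' `options(smdnaseq.reference_fasta = ...)`) and otherwise tries to download
#' it from NCBI efetch, which requires network access.
#'
#' @param accession RefSeq accession (default `"NC_012971.2"`).
#' @return path to a FASTA file containing the chromosome.
#' @export
fetch_reference_genome <- function(accession = "NC_012971.2") {
  opt <- getOption("smdnaseq.reference_fasta", NULL)
  if (!is.null(opt) && file.exists(opt)) return(opt)
  cache <- tools::R_user_dir("smdnaseq", "cache")
  dest <- file.path(cache, paste0(accession, ".fa"))
  if (file.exists(dest)) return(dest)
  dir.create(cache, showWarnings = FALSE, recursive = TRUE)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession, "&rettype=fasta&retmode=text")
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) < 1e6) {
    unlink(dest)
    stop("reference genome ", accession, " is not cached and could not be ",
         "downloaded; place the FASTA at '", dest, "' or set ",
         "options(smdnaseq.reference_fasta = <path>)")
  }
  dest
}
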