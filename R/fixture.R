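# Packaged fixture transcribing the published DISS identification table
# (27 adduct-ion rows over metabolites M0-M19; 7 metabolites were
# detected in both polarities). Printed ppm errors and the printed
# "Exact Mass" column are retained as provenance only: the package
# always recomputes masses from the formulas.

#' Load the packaged identification-table fixture
#'
#' Returns the adduct-ion rows of the published DISS metabolite summary
#' (retention time, polarity, adduct, measured m/z, adopted and printed
#' neutral compositions, printed ppm error, per-group matrix codes), the
#' printed MS2 fragment peaks, the per-metabolite distribution records,
#' and the fragment peak lists as spectra. File integrity is guarded by
#' stored MD5 digests.
#'
#' M19's adopted composition is C27H36O19 (consistent with the printed
#' m/z and the narrative C7H6-loss assignment); the summary table's
#' C31H36O16 is kept in `table_formula`.
#'
#' @param check_digest Verify packaged-file MD5 digests (default TRUE).
#' @return List: `features` (27-row data.frame), `fragments`
#'   (fragment-peak data.frame), `spectra` (named list keyed by
#'   feature id, [read_mgf()] shape), `distribution`
#'   ([distribution_records()] output).
#' @export
load_table1_fixture <- function(check_digest = TRUE) {
  ext <- function(f) system.file("extdata", f, package = "dissmet")
  paths <- c(features = ext("table1_features.tsv"),
             fragments = ext("table1_fragments.tsv"),
             mgf = ext("table1_ms2.mgf"))
  if (any(!nzchar(paths))) stop("packaged fixture files not found")
  if (check_digest) {
    digest_file <- ext("table1_checksums.tsv")
    expected <- utils::read.delim(digest_file, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(expected))) {
      actual <- unname(tools::md5sum(ext(expected$file[i])))
      if (!identical(actual, expected$md5[i])) {
        stop("fixture checksum mismatch for ", expected$file[i])
      }
    }
  }
  features <- read_feature_table(paths[["features"]])
  fragments <- read_table_file(paths[["fragments"]],
                               c("feature_id", "mz", "intensity",
                                 "printed_formula"))
  fragments$mz <- as.numeric(fragments$mz)
  fragments$intensity <- as.numeric(fragments$intensity)
  spectra <- read_mgf(paths[["mgf"]])
  list(features = features, fragments = fragments, spectra = spectra,
       distribution = distribution_records(features))
}
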