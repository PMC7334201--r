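Package: reelscreen
Title: Analysis and Simulation of Cyclic Gel-Shift (Reel-seq) Functional SNP Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying functional SNPs (fSNPs) from cyclic
    EMSA-based selection screens of synthetic SNP libraries. Covers the full
    computational arm of such a screen: representation and validation of
    SNP-centered oligo libraries, exact-match counting of barcoded amplicon
    reads into per-allele count matrices, completeness quality control,
    allele-ratio statistics (two-sample Student's t test at the final cycle,
    normalized sample/control ratio trajectories, per-cycle slope fitting and
    candidate/putative/non-fSNP classification), and spectral-count filtering
    of DNA-pulldown mass-spectrometry tables to call fSNP-specific binding
    proteins. A forward simulator of the selection process (allele-specific
    shift probabilities, independent replicate lineages, PCR regeneration,
    multinomial sequencing) generates fully labelled synthetic data so every
    stage can be tested against closed-form expectations and known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
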