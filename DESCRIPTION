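Package: ethanolMRS
Title: Brain Ethanol Quantification from Single-Voxel Proton MRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Determines brain ethanol concentrations from single-voxel proton
    magnetic resonance spectra. Implements linear-combination fitting of
    metabolite basis spectra under nonnegativity constraints with Cramer-Rao
    lower bounds as the precision measure, absolute quantification against an
    unsuppressed internal water reference, and normalization to the voxel
    water content derived from gray-matter, white-matter and
    cerebrospinal-fluid volume fractions. Includes Widmark-model serum ethanol
    pharmacokinetics for dose calculation and brain-versus-serum comparison,
    a synthetic-data generator emulating 3 T spectra at 74 ms echo time, and
    the packaged drinking-study tables (three volunteers, four brain regions,
    two measurement cycles).
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
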