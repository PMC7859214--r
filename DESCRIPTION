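Package: vertperf
Title: Lumbar Vertebral Perfusion Quantification from DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying lumbar vertebral bone-marrow perfusion from
    axial dynamic contrast-enhanced MRI. Implements variable-flip-angle T1
    mapping for spoiled gradient-echo acquisitions, closed-form conversion of
    dynamic signal to gadolinium concentration, construction of aortic,
    segmental-arterial and population-normalized (Parker-style) arterial input
    functions with first-pass bolus model fitting, extended Tofts model fitting
    of tissue curves both pixel-wise and ROI-based, a sensitivity study of
    perfusion parameters to the peak and delay of the arterial input function,
    nonparametric group comparisons (Wilcoxon signed-rank, Mann-Whitney,
    Kruskal-Wallis with Dunn-Bonferroni post hoc), and a digital phantom with
    known ground truth emulating the aorta / segmental artery / vertebra
    geometry of an axial lumbar slice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
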