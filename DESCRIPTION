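Package: mangroveyield
Title: Growth, Yield and Direct-Use Valuation of Restored Mangrove Stands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forest-mensuration and ecosystem-service valuation toolkit for
    even-aged mangrove stands (Rhizophora apiculata). Computes form-factor
    stem and stand volumes, mean and periodic annual increment (MAI/PAI)
    series and their culmination age from stand tables; simulates low
    thinning at tree level and quantifies pre/post-thinning stocking and
    MAI contrasts; and implements a direct-use valuation layer with nominal
    rate of return, Sturges income classing, per-person-per-day income
    conversion and a wood-versus-fishing income comparison. Includes a
    synthetic stand-trajectory and household-income generator so the whole
    pipeline is testable without field data, and a packaged scenario for a
    restored stand in Balikpapan Bay, East Kalimantan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
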