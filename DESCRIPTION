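Package: cmrdiastole
Title: Diastolic Function Assessment from Cardiovascular MRI Velocity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify left-ventricular diastolic function from
    cardiovascular magnetic resonance (CMR) phase-contrast and cine data and
    to compare the results against transthoracic echocardiography (TTE).
    Extracts transmitral peak velocities (E, A), the E-wave deceleration
    time, and mitral annular early-diastolic velocities (e') from velocity
    waveforms and tracked annulus insertion points; computes biplane
    area-length left-atrial volume indexed to body surface area (LAVi);
    grades diastolic dysfunction with configurable guideline or CMR-analog
    cutoff sets and calibrates CMR cutoffs from paired data by ROC analysis;
    and provides the method-agreement layer (Bland-Altman limits of
    agreement, Cohen's kappa, sensitivity and specificity with exact binomial
    confidence intervals, intraclass correlation, and multivariable logistic
    modelling with backward selection and leave-one-out validation).
    Includes a synthetic-data generator producing retrospectively-gated
    velocity waveforms, annulus displacement tracks, atrial geometry and
    paired-modality cohorts with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
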