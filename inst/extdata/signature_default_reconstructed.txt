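# Default 20-miRNA haemolysis signature -- RECONSTRUCTED set.
#
# This file is a curated stand-in for the originally validated 20-member
# red-blood-cell signature, whose full identities are not shipped with this
# package. Provenance per member:
#   [anchored]  named as Haemolysis-Metric-associated in published public-data
#               reproduction tables;
#   [curated]   mature miRNAs repeatedly reported as red-blood-cell-enriched
#               and/or haemolysis-susceptible in the plasma miRNA QC
#               literature (e.g. miR-451a and miR-486-5p are canonical
#               erythrocyte miRNAs; miR-16-5p and miR-92a-3p are classic
#               haemolysis indicators).
# Users reproducing published results should replace this file with the
# original signature list (read_signature()).
hsa-miR-451a      # curated
hsa-miR-486-5p    # curated
hsa-miR-16-5p     # curated
hsa-miR-92a-3p    # curated
hsa-miR-25-3p     # curated
hsa-miR-15b-5p    # curated
hsa-miR-106b-3p   # curated
hsa-miR-17-5p     # curated
hsa-miR-20a-5p    # curated
hsa-miR-106a-5p   # curated
hsa-miR-93-5p     # curated
hsa-miR-19b-3p    # curated
hsa-miR-191-5p    # anchored
hsa-miR-30c-5p    # anchored
hsa-miR-22-3p     # curated
hsa-miR-181a-5p   # curated
hsa-miR-142-5p    # curated
hsa-miR-144-3p    # curated
hsa-miR-363-3p    # curated
hsa-miR-484       # curated
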