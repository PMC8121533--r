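^SERIES = GSE900001
!Series_title = Single cell RNA-seq of human melanoma and spleen
!Series_geo_accession = GSE900001
!Series_summary = We performed droplet-based single cell RNA sequencing of melanoma biopsies.
!Series_overall_design = scRNA-seq of dissociated tumors, 10x Genomics
!Series_type = Expression profiling by high throughput sequencing
!Series_submission_date = Sep 18 2019
!Series_pubmed_id = 31588021
!Series_supplementary_file = ftp://ftp.ncbi.nlm.nih.gov/geo/series/GSE900nnn/GSE900001/suppl/GSE900001_human_melanoma_cell_metadata_9315x14.tsv.gz
!Series_supplementary_file = ftp://ftp.ncbi.nlm.nih.gov/geo/series/GSE900nnn/GSE900001/suppl/GSE900001_counts.tsv.gz
^SERIES = GSE900002
!Series_title = SuperSeries of cortex single nuclei profiling
!Series_geo_accession = GSE900002
!Series_summary = This SuperSeries is composed of the SubSeries listed below. snRNA-seq of mouse cortex.
!Series_overall_design = Refer to individual Series
!Series_type = Expression profiling by high throughput sequencing
!Series_submission_date = Mar 02 2020
!Series_relation = SuperSeries of: GSE900003
!Series_relation = SuperSeries of: GSE900004
^SERIES = GSE900003
!Series_title = Cortex single nuclei RNA-seq, batch 1
!Series_geo_accession = GSE900003
!Series_summary = snRNAseq of mouse cortex, first batch.
!Series_overall_design = single nuclei sequencing
!Series_type = Expression profiling by high throughput sequencing
!Series_submission_date = Mar 03 2020
!Series_pubmed_id = 32433969
!Series_relation = SubSeries of: GSE900002
!Series_supplementary_file = ftp://ftp.ncbi.nlm.nih.gov/geo/series/GSE900nnn/GSE900003/suppl/GSE900003_matrix.mtx.gz
!Sample_supplementary_file_1 = ftp://ftp.ncbi.nlm.nih.gov/geo/samples/GSM100nnn/GSM1000001/suppl/GSM1000001_barcodes.tsv.gz
^SERIES = GSE900004
!Series_title = Cortex single nuclei RNA-seq, batch 2
!Series_geo_accession = GSE900004
!Series_summary = snRNAseq of mouse cortex, second batch with annotations.
!Series_overall_design = single nuclei sequencing
!Series_type = Expression profiling by high throughput sequencing
!Series_submission_date = Mar 04 2020
!Series_relation = SubSeries of: GSE900002
!Series_supplementary_file = ftp://ftp.ncbi.nlm.nih.gov/geo/series/GSE900nnn/GSE900004/suppl/GSE900004_cell_annotations.tsv.gz
^SERIES = GSE900005
!Series_title = Bulk RNA-seq of sorted immune populations
!Series_geo_accession = GSE900005
!Series_summary = Bulk transcriptome profiling of FACS sorted populations.
!Series_overall_design = bulk RNA sequencing of sorted cells
!Series_type = Expression profiling by high throughput sequencing
!Series_submission_date = Jan 10 2018
!Series_supplementary_file = ftp://ftp.ncbi.nlm.nih.gov/geo/series/GSE900nnn/GSE900005/suppl/GSE900005_fpkm_table.txt.gz
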