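<?xml version="1.0" encoding="UTF-8"?>
<eSummaryResult>
  <DocSum>
    <Id>200900010</Id>
    <Item Name="Accession" Type="String">GSE900010</Item>
    <Item Name="title" Type="String">scRNA-seq atlas of zebrafish retina</Item>
    <Item Name="summary" Type="String">Single cell RNA-seq across developmental stages.</Item>
    <Item Name="gdsType" Type="String">Expression profiling by high throughput sequencing</Item>
    <Item Name="PDAT" Type="String">2020/07/21</Item>
    <Item Name="suppFile" Type="String">GSE900010_retina_metadata.tsv.gz; GSE900010_counts.mtx.gz</Item>
    <Item Name="PubMedIds" Type="List">
      <Item Name="int" Type="Integer">32555229</Item>
    </Item>
  </DocSum>
  <DocSum>
    <Id>200900011</Id>
    <Item Name="Accession" Type="String">GSE900011</Item>
    <Item Name="title" Type="String">Single cell profiling of human PBMC</Item>
    <Item Name="summary" Type="String">10x Genomics scRNAseq of PBMC.</Item>
    <Item Name="gdsType" Type="String">Expression profiling by high throughput sequencing</Item>
    <Item Name="PDAT" Type="String">2019/11/02</Item>
    <Item Name="suppFile" Type="String">GSE900011_raw_counts.tsv.gz</Item>
  </DocSum>
</eSummaryResult>
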