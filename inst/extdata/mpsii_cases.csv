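case_id,publication_id,publication_date,publication_type,in_clinical_meta_analysis,aggregated_form,outcome_id,reported,improvement_mentioned,method_described,quantitative_measure,irr_dose_change
c01,P01,2008-06-15,article,true,false,antibodies,true,true,true,false,false
c02,P01,2008-06-15,article,true,false,6mwt,true,true,false,true,false
c03,P01,2008-06-15,article,true,false,6mwt,true,true,false,false,false
c04,P01,2008-06-15,article,true,false,6mwt,true,true,false,false,false
c04,P01,2008-06-15,article,true,false,ugags,true,true,false,true,false
c05,P02,2010-03-20,article,true,false,jrom,true,true,true,false,false
c05,P02,2010-03-20,article,true,false,ugags,true,true,true,false,false
c06,P02,2010-03-20,article,true,false,growth,true,true,false,true,false
c06,P02,2010-03-20,article,true,false,ugags,true,true,false,true,false
c07,P02,2010-03-20,article,true,false,growth,true,true,false,false,false
c07,P02,2010-03-20,article,true,false,ugags,true,true,true,false,false
c08,P02,2010-03-20,article,true,false,irr,true,false,false,false,true
c08,P02,2010-03-20,article,true,false,ugags,true,true,false,true,false
c09,P03,2011-09-10,article,true,false,liver_vol,true,true,true,false,false
c09,P03,2011-09-10,article,true,false,pulmonary,true,true,false,false,false
c10,P03,2011-09-10,article,true,false,liver_vol,true,true,false,true,false
c10,P03,2011-09-10,article,true,false,qol,true,true,false,false,false
c11,P03,2011-09-10,article,true,false,liver_vol,true,true,false,false,false
c11,P03,2011-09-10,article,true,false,qol,true,true,false,false,false
c12,P04,2009-05-01,article,false,false,6mwt,true,true,false,false,false
c12,P04,2009-05-01,article,false,false,ugags,true,true,false,true,false
c13,P04,2009-05-01,article,false,false,6mwt,true,true,false,false,false
c13,P04,2009-05-01,article,false,false,ugags,true,true,true,false,false
c14,P05,2010-07-15,article,false,false,6mwt,true,true,false,false,false
c14,P05,2010-07-15,article,false,false,ugags,true,true,false,true,false
c15,P05,2010-07-15,article,false,false,6mwt,true,true,false,false,false
c15,P05,2010-07-15,article,false,false,ugags,true,true,true,false,false
c16,P06,2011-02-28,article,false,false,6mwt,true,true,false,false,false
c16,P06,2011-02-28,article,false,false,ugags,true,true,false,true,false
c17,P06,2011-02-28,article,false,false,6mwt,true,true,false,false,false
c17,P06,2011-02-28,article,false,false,ugags,true,true,true,false,false
c18,P07,2012-04-10,article,false,false,jrom,true,true,false,true,false
c18,P07,2012-04-10,article,false,false,ugags,true,true,false,true,false
c19,P07,2012-04-10,article,false,false,jrom,true,true,true,false,false
c19,P07,2012-04-10,article,false,false,ugags,true,true,true,false,false
c20,P08,2012-11-05,article,false,false,jrom,true,true,false,false,false
c20,P08,2012-11-05,article,false,false,ugags,true,true,false,true,false
c21,P08,2012-11-05,article,false,false,growth,true,true,true,false,false
c21,P08,2012-11-05,article,false,false,ugags,true,true,true,false,false
c22,P09,2013-06-22,article,false,false,growth,true,true,false,true,false
c22,P09,2013-06-22,article,false,false,ugags,true,true,false,true,false
c23,P09,2013-06-22,article,false,false,growth,true,true,false,false,false
c23,P09,2013-06-22,article,false,false,ugags,true,true,true,false,false
c24,P10,2014-01-30,article,false,false,irr,true,false,false,false,true
c24,P10,2014-01-30,article,false,false,liver_vol,true,true,false,true,false
c25,P10,2014-01-30,article,false,false,liver_vol,true,true,true,false,false
c25,P10,2014-01-30,article,false,false,pulmonary,true,true,true,false,false
c26,P11,2009-10-12,article,false,false,liver_vol,true,true,false,true,false
c26,P11,2009-10-12,article,false,false,pulmonary,true,true,false,false,false
c27,P12,2010-12-01,article,false,false,liver_vol,true,true,true,false,false
c27,P12,2010-12-01,article,false,false,pulmonary,true,true,false,false,false
c28,P13,2011-06-18,article,false,false,liver_vol,true,true,false,true,false
c28,P13,2011-06-18,article,false,false,qol,true,true,false,false,false
c29,P14,2012-08-25,article,false,false,liver_vol,true,true,false,false,false
c29,P14,2012-08-25,article,false,false,qol,true,true,false,false,false
c30,P15,2013-03-14,article,false,false,liver_vol,true,true,false,false,false
c30,P15,2013-03-14,article,false,false,qol,true,true,false,false,false
c31,P16,2013-09-09,article,false,false,liver_vol,true,true,false,false,false
c31,P16,2013-09-09,article,false,false,qol,true,true,false,false,false
c32,P17,2014-05-20,article,false,false,antibodies,true,true,false,true,false
c32,P17,2014-05-20,article,false,false,qol,true,true,false,false,false
c33,P18,2014-10-08,article,false,false,antibodies,true,true,true,false,false
c33,P18,2014-10-08,article,false,false,sleep_apnea,true,true,false,false,false
c34,P19,2015-02-17,article,false,false,antibodies,true,true,false,true,false
c35,P20,2015-07-29,article,false,false,6mwt,true,true,true,false,false
c36,P21,2015-11-30,article,false,false,6mwt,true,true,false,false,false
c37,P22,2013-04-05,congress_communication,false,false,antibodies,true,true,true,false,false
c38,P22,2013-04-05,congress_communication,false,false,6mwt,true,true,false,true,false
c39,P23,2014-03-18,congress_communication,false,false,6mwt,true,true,true,false,false
c39,P23,2014-03-18,congress_communication,false,false,ugags,true,true,true,false,false
c40,P23,2014-03-18,congress_communication,false,false,6mwt,true,true,false,false,false
c40,P23,2014-03-18,congress_communication,false,false,ugags,true,true,false,true,false
c41,P24,2015-04-22,congress_communication,false,false,6mwt,true,true,false,false,false
c41,P24,2015-04-22,congress_communication,false,false,ugags,true,true,true,false,false
c42,P24,2015-04-22,congress_communication,false,false,jrom,true,true,false,true,false
c42,P24,2015-04-22,congress_communication,false,false,liver_vol,true,true,false,true,false
c43,P25,2015-09-12,congress_communication,false,false,liver_vol,true,true,false,false,false
c43,P25,2015-09-12,congress_communication,false,false,qol,true,true,false,false,false
c44,P25,2015-09-12,congress_communication,false,false,antibodies,true,true,false,true,false
c45,P26,2016-01-15,article,false,false,liver_vol,true,true,true,false,false
c45,P26,2016-01-15,article,false,false,pulmonary,true,true,false,false,false
c46,P27,2016-03-10,article,false,false,liver_vol,true,true,false,true,false
c46,P27,2016-03-10,article,false,false,sleep_apnea,true,true,false,true,false
c47,P28,2016-05-25,article,false,false,liver_vol,true,true,false,false,false
c48,P29,2016-08-30,article,false,false,antibodies,true,true,false,true,false
c49,P30,2016-11-12,article,false,false,antibodies,true,true,true,false,false
c50,P31,2017-02-07,article,false,false,6mwt,true,true,false,true,false
c51,P32,2017-04-19,article,false,false,6mwt,true,true,true,false,false
c52,P33,2017-07-03,article,false,false,6mwt,true,true,false,false,false
c52,P33,2017-07-03,article,false,false,ugags,true,true,false,true,false
c53,P34,2017-09-28,article,false,false,6mwt,true,true,false,false,false
c53,P34,2017-09-28,article,false,false,ugags,true,true,true,false,false
c54,P35,2017-12-15,article,false,false,jrom,true,true,false,true,false
c54,P35,2017-12-15,article,false,false,ugags,true,true,false,true,false
c55,P36,2018-02-20,article,false,false,growth,true,true,true,false,false
c55,P36,2018-02-20,article,false,false,ugags,true,true,true,false,false
c56,P37,2018-03-30,article,false,false,liver_vol,true,true,false,true,false
c56,P37,2018-03-30,article,false,false,pulmonary,true,true,false,true,false
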